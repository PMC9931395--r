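# Minimal NIfTI-1 I/O.
#
# No NIfTI package is available in the supported dependency set, so the
# package carries its own single-file (.nii / .nii.gz) reader and writer:
# the fixed 348-byte header, float32/float64/int16/uint8 payloads, 3D or 4D
# volumes, srow affine, scl_slope/scl_inter. That subset round-trips every
# file this package writes and covers typical quantitative-MRI exports.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nifti_connection <- function(path, open) {
  gz <- grepl("\\.gz$", path)
  if (gz) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii`, optionally gzipped) into a
#' [volume_map] (3D) or a plain list with a 4D array (`values`, `affine`).
#'
#' @param path file path.
#' @param role role tag to attach to the returned map.
#' @return For 3D images a `volume_map`; for 4D images a list with elements
#'   `values` (4D array) and `affine`.
#' @export
read_volume <- function(path, role = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop(path, " is not a NIfTI-1 file",
                                   call. = FALSE)
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = "little")
  }
  sizeof_hdr <- rd(0, "integer", 1, 4)
  if (sizeof_hdr != 348L) stop(path, " is not a little-endian NIfTI-1 file",
                               call. = FALSE)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, " lacks the NIfTI magic",
                                        call. = FALSE)
  dim0 <- rd(40, "integer", 8, 2)
  ndim <- dim0[1]
  if (!ndim %in% c(3L, 4L)) stop("only 3D/4D NIfTI supported, got ", ndim,
                                 "D", call. = FALSE)
  dims <- dim0[2:(1 + ndim)]
  datatype <- rd(70, "integer", 1, 2)
  spec <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype,
                          call. = FALSE)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "double", 12, 4), nrow = 3, byrow = TRUE)
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code <= 0L) affine <- diag(c(pixdim[2:4], 1))
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(vals) != n) stop("truncated NIfTI payload in ", path,
                              call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(as.double(vals), dim = dims)
  if (ndim == 3L) volume_map(arr, affine = affine, role = role)
  else list(values = arr, affine = affine, role = role)
}

#' Write a NIfTI-1 volume
#'
#' Writes a [volume_map] (or a 3D/4D array plus affine) as a single-file
#' little-endian NIfTI-1 image, float64 by default so that round trips are
#' bit-exact.
#'
#' @param map a `volume_map`, or a numeric 3D/4D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 affine (required when `map` is a bare array).
#' @param datatype `"float64"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path, affine = NULL, datatype = "float64") {
  if (is_volume_map(map)) {
    arr <- map$values
    affine <- map$affine
  } else {
    arr <- map
    if (is.null(affine)) affine <- diag(4)
  }
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L)) stop("only 3D/4D arrays supported", call. = FALSE)
  code <- switch(datatype, float64 = 64L, float32 = 16L,
                 stop("unsupported datatype ", datatype, call. = FALSE))
  spec <- nifti_datatypes[[as.character(code)]]
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(arr)
  dims[(2 + nd):8] <- 1L
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(1, vox, rep(1, 4))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wr <- function(x, size, what = "integer")
    writeBin(if (what == "integer") as.integer(x) else as.double(x), con,
             size = size, endian = "little")
  wr(348L, 4)                         # sizeof_hdr
  writeBin(raw(36), con)              # data_type, db_name, extents, ...
  wr(dims, 2)                         # dim[8]
  wr(rep(0, 3), 4, "double")          # intent_p1..p3
  wr(0L, 2)                           # intent_code
  wr(code, 2)                         # datatype
  wr(spec$bitpix, 2)                  # bitpix
  wr(0L, 2)                           # slice_start
  wr(pixdim, 4, "double")             # pixdim[8]
  wr(352, 4, "double")                # vox_offset
  wr(1, 4, "double")                  # scl_slope
  wr(0, 4, "double")                  # scl_inter
  wr(0L, 2); writeBin(raw(2), con)    # slice_end, slice_code, xyzt_units
  wr(rep(0, 3), 4, "double")          # cal_max, cal_min, slice_duration
  wr(0, 4, "double")                  # toffset
  wr(c(0L, 0L), 4)                    # glmax, glmin
  writeBin(raw(80 + 24), con)         # descrip, aux_file
  wr(0L, 2)                           # qform_code
  wr(1L, 2)                           # sform_code
  wr(rep(0, 6), 4, "double")          # quaternions
  wr(t(affine[1:3, , drop = FALSE]), 4, "double")  # srow_x/y/z
  writeBin(raw(16), con)              # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)               # extension flag
  writeBin(as.double(arr), con, size = spec$size, endian = "little")
  invisible(path)
}

#' Read a 4D NIfTI plus JSON sidecar as an echo series
#'
#' Echo times are carried in a JSON sidecar (same basename, `.json`
#' extension) with fields `echo_times_ms` or `echo_spacing_ms`.
#'
#' @param path 4D NIfTI path.
#' @param mask optional 3D mask NIfTI path; default: all voxels with finite
#'   nonzero first-echo signal.
#' @return An [echo_series] object.
#' @export
read_echo_series <- function(path, mask = NULL) {
  x <- read_volume(path)
  if (is_volume_map(x)) stop(path, " is 3D; an echo series must be 4D",
                             call. = FALSE)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    stop("echo-time sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_echo <- dim(x$values)[4]
  te <- if (!is.null(meta$echo_times_ms)) as.numeric(meta$echo_times_ms)
        else if (!is.null(meta$echo_spacing_ms))
          seq_len(n_echo) * as.numeric(meta$echo_spacing_ms)
        else stop("sidecar must provide echo_times_ms or echo_spacing_ms",
                  call. = FALSE)
  m <- if (is.null(mask)) {
    e1 <- x$values[, , , 1]
    is.finite(e1) & e1 > 0
  } else {
    mm <- read_volume(mask, role = "mask")
    check_same_grid(volume_map(x$values[, , , 1], x$affine), mm)
    vol_values(mm) > 0.5
  }
  echo_series(x$values, echo_times = te, mask = m, affine = x$affine)
}

#' Write an echo series with its JSON sidecar
#' @param series an [echo_series].
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_echo_series <- function(series, path) {
  stopifnot(inherits(series, "echo_series"))
  write_volume(series$data, path, affine = series$affine)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(echo_times_ms = series$echo_times,
                            echo_spacing_ms = series$echo_spacing),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
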