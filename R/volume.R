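#' Volume maps
#'
#' A `volume_map` is the package's container for a named 3D scalar map on a
#' subject's voxel grid: a numeric array plus a 4x4 affine, a role (what
#' quantity the map holds, e.g. `"MWF_NNLS"`, `"ihMTR"`, `"g"`) and units.
#' Invalid voxels are encoded as `NaN` and are excluded from all VOI
#' statistics and calibrations.
#'
#' @param values numeric 3D array.
#' @param affine 4x4 voxel-to-world transform; default scales by
#'   `voxel_size_mm`.
#' @param role character role tag from [volume_roles()].
#' @param units character units string (`""` for dimensionless fractions).
#' @param voxel_size_mm length-3 voxel size used to build the default affine.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(values, affine = NULL, role = "unknown", units = "",
                       voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(values = values, affine = affine, role = role,
                 units = units),
            class = "volume_map")
}

#' Registered role vocabulary for volume maps
#' @return character vector of known roles.
#' @export
volume_roles <- function() {
  c("MWF_NNLS", "MWF_SPIJN", "MWF_true", "ihMTR", "MTsat", "R1", "A_app",
    "PD", "MTV", "MVF", "AVF", "NMVF", "g", "v_ic", "v_iso", "mask",
    "labels", "M0", "unknown")
}

#' @export
print.volume_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<volume_map role=%s units=%s dim=%s>\n", x$role,
              if (nzchar(x$units)) x$units else "-",
              paste(dim(v), collapse = "x")))
  ok <- is.finite(v)
  cat(sprintf("  valid voxels: %d/%d, range [%.4g, %.4g]\n", sum(ok),
              length(v), suppressWarnings(min(v[ok])),
              suppressWarnings(max(v[ok]))))
  invisible(x)
}

#' @rdname volume_map
#' @param x object to test or coerce.
#' @export
is_volume_map <- function(x) inherits(x, "volume_map")

#' Extract the value array of a volume map (or pass arrays through)
#' @param x a `volume_map` or a 3D array.
#' @return the numeric 3D array.
#' @export
vol_values <- function(x) {
  if (is_volume_map(x)) x$values else x
}

# Build a map on the same grid/affine as a template, replacing values/role.
vol_like <- function(template, values, role = NULL, units = NULL) {
  stopifnot(is_volume_map(template))
  volume_map(values, affine = template$affine,
             role = role %||% template$role,
             units = units %||% template$units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_same_grid <- function(...) {
  maps <- list(...)
  dims <- lapply(maps, function(m) dim(vol_values(m)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
    stop("maps do not share one voxel grid: ",
         paste(unique(vapply(dims, paste, "", collapse = "x")),
               collapse = " vs "), call. = FALSE)
  invisible(TRUE)
}
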