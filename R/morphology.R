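# Binary 3D mask morphology with the 6-connected (face-neighbor)
# structuring element, used to build analysis VOIs: lesion erosion,
# perilesional shells, lesion shells, and connected-component labeling.

# shift a 3D array by one voxel along an axis, padding with `fill`
shift3d <- function(x, axis, by, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Erode a binary mask
#'
#' One iteration removes every voxel that has at least one of its six
#' face-neighbors (or a volume boundary) outside the mask.
#'
#' @param mask logical 3D array.
#' @param iterations number of erosion passes, default 1.
#' @return logical 3D array.
#' @export
erode_mask <- function(mask, iterations = 1) {
  m <- as_mask(mask)
  for (k in seq_len(iterations)) {
    keep <- m
    for (axis in 1:3) for (by in c(-1L, 1L))
      keep <- keep & shift3d(m, axis, by, fill = FALSE)
    m <- keep
  }
  m
}

#' Dilate a binary mask
#'
#' One iteration adds every voxel with at least one face-neighbor inside
#' the mask.
#'
#' @inheritParams erode_mask
#' @return logical 3D array.
#' @export
dilate_mask <- function(mask, iterations = 1) {
  m <- as_mask(mask)
  for (k in seq_len(iterations)) {
    grow <- m
    for (axis in 1:3) for (by in c(-1L, 1L))
      grow <- grow | shift3d(m, axis, by, fill = FALSE)
    m <- grow
  }
  m
}

as_mask <- function(mask) {
  m <- vol_values(mask)
  if (length(dim(m)) != 3L) stop("mask must be 3D", call. = FALSE)
  array(as.logical(m), dim(m))
}

#' Perilesional shell
#'
#' A `width`-voxel-wide shell of normal-appearing white matter surrounding
#' lesions: `(dilate(lesion, width) \\ lesion)` intersected with the WM
#' mask.
#'
#' @param lesion_mask,wm_mask logical 3D arrays on one grid.
#' @param width shell width in voxels, default 2.
#' @return logical 3D array, disjoint from the lesion mask.
#' @export
make_perilesion <- function(lesion_mask, wm_mask, width = 2) {
  les <- as_mask(lesion_mask)
  wm <- as_mask(wm_mask)
  check_same_grid(les, wm)
  dilate_mask(les, width) & !les & wm
}

#' Lesion shell
#'
#' The outermost one-voxel-wide layer of each lesion:
#' `lesion \\ erode(lesion, 1)`.
#'
#' @param lesion_mask logical 3D array.
#' @return logical 3D array (subset of the lesion mask).
#' @export
make_lesion_shell <- function(lesion_mask) {
  les <- as_mask(lesion_mask)
  les & !erode_mask(les, 1)
}

#' Label connected components (6-connectivity)
#'
#' @param mask logical 3D array.
#' @return integer 3D array: 0 outside, 1..k per component.
#' @export
label_components <- function(mask) {
  m <- as_mask(mask)
  lab <- array(0L, dim(m))
  comp <- 0L
  todo <- m
  while (any(todo)) {
    comp <- comp + 1L
    seedv <- array(FALSE, dim(m))
    seedv[which(todo)[1]] <- TRUE
    repeat {
      grown <- dilate_mask(seedv) & m
      if (sum(grown) == sum(seedv)) break
      seedv <- grown
    }
    lab[seedv] <- comp
    todo <- todo & !seedv
  }
  lab
}

#' Threshold probability maps into VOI masks
#'
#' Lesions are voxels with lesion probability strictly greater than
#' `lesion_threshold`; tissue masks are thresholded at strictly greater
#' than `tissue_threshold`, and lesion-probability voxels above the lesion
#' threshold are excluded from every non-lesion mask.
#'
#' @param tissue_probabilities named list of 3D probability maps in [0, 1]
#'   (e.g. `WM`, `GM`, `CSF`).
#' @param lesion_probability 3D lesion probability map (optional).
#' @param lesion_threshold,tissue_threshold strict thresholds, defaults
#'   0.5 and 0.9.
#' @return named list of logical masks (plus `lesion` if a lesion
#'   probability was given).
#' @export
threshold_masks <- function(tissue_probabilities,
                            lesion_probability = NULL,
                            lesion_threshold = 0.5,
                            tissue_threshold = 0.9) {
  pr <- lapply(tissue_probabilities, vol_values)
  bad <- vapply(pr, function(p) any(p < 0 | p > 1, na.rm = TRUE), TRUE)
  if (any(bad)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  lesion <- NULL
  if (!is.null(lesion_probability)) {
    lp <- vol_values(lesion_probability)
    if (any(lp < 0 | lp > 1, na.rm = TRUE))
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    lesion <- lp > lesion_threshold
  }
  out <- lapply(pr, function(p) {
    m <- p > tissue_threshold
    if (!is.null(lesion)) m <- m & !lesion
    m
  })
  if (!is.null(lesion)) out$lesion <- lesion
  out
}
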