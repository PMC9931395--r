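#' Multi-echo series container
#'
#' Holds 4D multi-echo magnitude data with echo-time metadata, the input to
#' myelin water fraction fitting. Echo times must be strictly increasing and
#' uniformly spaced (a CPMG train).
#'
#' @param data 4D nonnegative array (x, y, z, echo).
#' @param echo_times numeric vector of echo times in ms.
#' @param mask 3D logical array of voxels to fit.
#' @param affine 4x4 affine.
#' @return An `echo_series` object.
#' @export
echo_series <- function(data, echo_times, mask = NULL, affine = diag(4)) {
  if (length(dim(data)) != 4L)
    stop("`data` must be 4D (x, y, z, echo)", call. = FALSE)
  n_echo <- dim(data)[4]
  if (length(echo_times) != n_echo)
    stop("echo count mismatch: ", length(echo_times), " echo times for ",
         n_echo, " volumes", call. = FALSE)
  d <- diff(echo_times)
  if (any(d <= 0) || diff(range(d)) > 1e-6 * d[1])
    stop("echo times must be strictly increasing and uniformly spaced",
         call. = FALSE)
  if (any(data[is.finite(data)] < 0))
    stop("magnitude data must be nonnegative", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 echo_spacing = d[1], mask = mask, affine = affine),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat(sprintf("<echo_series %s, %d echoes, ESP %.3g ms, %d masked voxels>\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$echo_spacing, sum(x$mask)))
  invisible(x)
}

#' Logarithmic T2 grid with a myelin water window
#'
#' The support of the fitted T2 distribution. The short-T2 ("myelin water")
#' window defines the MWF summary: MWF = sum of amplitudes with
#' T2 <= `window_max` over the total amplitude. Defaults (40 points,
#' 10-2000 ms, window <= 40 ms) are the community-standard choices for
#' 3 T multi-echo spin-echo myelin water imaging.
#'
#' @param t2_min,t2_max grid range in ms.
#' @param n_t2 number of grid points (>= 2).
#' @param window_max upper edge of the myelin water window in ms.
#' @return A `t2_grid` object.
#' @export
t2_grid <- function(t2_min = 10, t2_max = 2000, n_t2 = 40, window_max = 40) {
  stopifnot(t2_min > 0, t2_max > t2_min, n_t2 >= 2)
  t2 <- exp(seq(log(t2_min), log(t2_max), length.out = n_t2))
  if (window_max <= t2_min || window_max >= t2_max)
    stop("myelin window must lie inside the grid range", call. = FALSE)
  if (sum(t2 <= window_max) < 2)
    stop("need at least 2 grid points inside the myelin window",
         call. = FALSE)
  structure(list(t2_values = t2, myelin_window = c(t2_min, window_max)),
            class = "t2_grid")
}

#' EPG sequence parameters
#'
#' @param refocusing_flip refocusing flip angle in degrees, in (0, 180].
#' @param t1_assumed assumed T1 in ms (damps stored longitudinal states;
#'   MWF is insensitive to this at 8 ms echo spacing).
#' @param echo_spacing echo spacing in ms.
#' @param n_echoes number of echoes.
#' @return An `epg_params` object.
#' @export
epg_params <- function(refocusing_flip = 180, t1_assumed = 1000,
                       echo_spacing = 8, n_echoes = 48) {
  if (refocusing_flip <= 0 || refocusing_flip > 180)
    stop("refocusing flip must be in (0, 180] degrees", call. = FALSE)
  if (t1_assumed <= 0) stop("t1_assumed must be > 0", call. = FALSE)
  if (echo_spacing <= 0) stop("echo spacing must be > 0", call. = FALSE)
  if (n_echoes < 2) stop("need at least 2 echoes", call. = FALSE)
  structure(list(refocusing_flip = refocusing_flip, t1_assumed = t1_assumed,
                 echo_spacing = echo_spacing, n_echoes = as.integer(n_echoes)),
            class = "epg_params")
}

#' EPG echo amplitudes of a CPMG train
#'
#' Extended-phase-graph recursion for the echo amplitudes of a multi-echo
#' spin-echo train with imperfect refocusing pulses; this is the forward
#' model underlying stimulated-echo-corrected myelin water imaging. At a
#' refocusing flip of 180 degrees it reduces exactly to
#' `exp(-TE_n / t2)`.
#'
#' @param t2 transverse relaxation time in ms (> 0).
#' @param params an [epg_params] object.
#' @return numeric vector of `n_echoes` echo amplitudes (unit initial
#'   magnetization).
#' @export
epg_decay_curve <- function(t2, params) {
  if (t2 <= 0) stop("t2 must be > 0", call. = FALSE)
  stopifnot(inherits(params, "epg_params"))
  drop(cpp_epg_curve(t2, params$t1_assumed, params$echo_spacing,
                     params$refocusing_flip, params$n_echoes))
}

#' Multi-exponential decay basis
#'
#' Column `j` is [epg_decay_curve()] evaluated at the j-th grid T2.
#'
#' @param grid a [t2_grid].
#' @param params an [epg_params].
#' @return `n_echoes` x `n_t2` matrix.
#' @export
build_decay_basis <- function(grid, params) {
  stopifnot(inherits(grid, "t2_grid"), inherits(params, "epg_params"))
  cpp_epg_basis(grid$t2_values, params$t1_assumed, params$echo_spacing,
                params$refocusing_flip, params$n_echoes)
}

#' Regularized NNLS T2-spectrum fit of one voxel
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0`, then, if
#' `reg_factor > 1`, selects a Tikhonov weight mu by bisection such that the
#' regularized data misfit (squared residual norm) equals
#' `reg_factor` times the unregularized minimum -- the conventional
#' chi-squared-inflation criterion for smooth T2 distributions.
#'
#' @param signal numeric echo vector.
#' @param basis decay basis from [build_decay_basis()].
#' @param reg_factor misfit inflation factor (>= 1); 1.02 by default.
#' @param grid optional [t2_grid] used to attach the MWF summary.
#' @return A `t2_spectrum`: list with `amplitudes`, `chi2`, `mu`, `mwf`
#'   (NA without a grid), and `invalid` flag. An all-zero signal yields a
#'   flagged-invalid spectrum, not an error.
#' @export
nnls_fit_voxel <- function(signal, basis, reg_factor = 1.02, grid = NULL) {
  if (length(signal) != nrow(basis))
    stop("signal length must equal basis rows", call. = FALSE)
  if (reg_factor < 1) stop("reg_factor must be >= 1", call. = FALSE)
  if (!any(is.finite(signal)) || sum(signal^2, na.rm = TRUE) == 0) {
    return(structure(list(amplitudes = rep(0, ncol(basis)), chi2 = NA_real_,
                          mu = NA_real_, mwf = NA_real_, invalid = TRUE),
                     class = "t2_spectrum"))
  }
  fit <- cpp_nnls_reg(basis, signal, reg_factor)
  amps <- drop(fit$x)
  mwf <- if (!is.null(grid)) mwf_from_spectrum(amps, grid) else NA_real_
  structure(list(amplitudes = amps, chi2 = fit$chi2, mu = fit$mu, mwf = mwf,
                 invalid = sum(amps) <= 0),
            class = "t2_spectrum")
}

# window rule shared by both algorithms
mwf_from_spectrum <- function(amplitudes, grid) {
  tot <- sum(amplitudes)
  if (tot <= 0) return(NA_real_)
  sum(amplitudes[grid$t2_values <= grid$myelin_window[2]]) / tot
}

#' Estimate the refocusing flip angle of one voxel
#'
#' Evaluates the unregularized NNLS misfit of the voxel signal against EPG
#' bases built for each candidate flip angle, fits a parabola through the
#' minimum and its neighbors, and returns the interpolated minimizing angle
#' clipped to the grid range. A flat misfit profile (e.g. a zero signal)
#' returns the grid minimum with `flat = TRUE`.
#'
#' @param signal numeric echo vector.
#' @param grid a [t2_grid].
#' @param params an [epg_params] (its `refocusing_flip` is ignored).
#' @param angle_grid candidate angles in degrees, within (90, 180], >= 3
#'   values; default 90-180 in 5 degree steps.
#' @return list with `flip` (degrees) and `flat` flag.
#' @export
estimate_flip_angle <- function(signal, grid, params,
                                angle_grid = seq(90, 180, by = 5)) {
  if (length(angle_grid) < 3) stop("need >= 3 candidate angles",
                                   call. = FALSE)
  if (any(angle_grid <= 0) || any(angle_grid > 180))
    stop("candidate angles must lie in (0, 180]", call. = FALSE)
  angle_grid <- sort(angle_grid)
  chi <- vapply(angle_grid, function(a) {
    A <- cpp_epg_basis(grid$t2_values, params$t1_assumed,
                       params$echo_spacing, a, params$n_echoes)
    cpp_nnls(A, signal)$chi2
  }, 0)
  b2 <- sum(signal^2)
  if (max(chi) - min(chi) <= 1e-12 * max(max(chi), b2)) {
    warning("flat misfit profile; returning grid minimum angle")
    return(list(flip = angle_grid[1], flat = TRUE))
  }
  m <- which.min(chi)
  if (m == 1L || m == length(chi))
    return(list(flip = angle_grid[m], flat = FALSE))
  y <- chi[(m - 1):(m + 1)]
  x <- angle_grid[(m - 1):(m + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  flip <- if (abs(denom) < .Machine$double.xmin) x[2]
          else x[2] + 0.5 * (x[3] - x[2]) * (y[1] - y[3]) / denom
  list(flip = min(max(flip, min(angle_grid)), max(angle_grid)), flat = FALSE)
}

#' Voxelwise regularized-NNLS myelin water fraction map
#'
#' Per masked voxel: estimate the refocusing flip angle (stimulated-echo
#' correction), rebuild the EPG basis at that angle, run the
#' chi-squared-inflation regularized NNLS, and summarize the spectrum into
#' MWF by the short-T2 window rule. Unmasked or degenerate voxels are NaN.
#'
#' @param series an [echo_series].
#' @param grid a [t2_grid].
#' @param params an [epg_params]; when `flip_correction = FALSE` its
#'   `refocusing_flip` is used for all voxels.
#' @param reg_factor misfit inflation factor, default 1.02.
#' @param flip_correction estimate a per-voxel flip angle (default TRUE).
#' @param angle_grid candidate flip angles.
#' @return A [volume_map] with role `"MWF_NNLS"`; attribute `fit` carries
#'   per-voxel flip angles and chi-squared values.
#' @export
fit_mwf_nnls <- function(series, grid, params, reg_factor = 1.02,
                         flip_correction = TRUE,
                         angle_grid = seq(90, 180, by = 5)) {
  stopifnot(inherits(series, "echo_series"), inherits(grid, "t2_grid"),
            inherits(params, "epg_params"))
  idx <- which(series$mask)
  if (length(idx) == 0) stop("mask is empty", call. = FALSE)
  nv <- length(idx)
  d4 <- dim(series$data)
  B <- matrix(aperm(series$data, c(4, 1, 2, 3)), nrow = d4[4])[, idx,
                                                               drop = FALSE]
  fit <- cpp_fit_mwf_batch(B, grid$t2_values, params$t1_assumed,
                           params$echo_spacing, sort(angle_grid),
                           reg_factor, flip_correction,
                           params$refocusing_flip)
  win <- grid$t2_values <= grid$myelin_window[2]
  tot <- colSums(fit$amplitudes)
  mwf <- ifelse(tot > 0, colSums(fit$amplitudes[win, , drop = FALSE]) / tot,
                NA_real_)
  mwf[fit$invalid] <- NA_real_
  out <- array(NaN, d4[1:3])
  out[idx] <- mwf
  map <- volume_map(out, affine = series$affine, role = "MWF_NNLS")
  attr(map, "fit") <- list(flip = fit$flip, chi2 = fit$chi2,
                           n_invalid = sum(fit$invalid),
                           n_flat = sum(fit$flat_profile))
  map
}

#' Joint-sparsity (SPIJN) myelin water fraction map
#'
#' Fits all masked voxels jointly with one shared EPG dictionary under a
#' row-sparsity penalty: `min sum_v ||A x_v - b_v||^2 +
#' lambda * sum_j w_j ||x_j.||`, solved by iteratively reweighted joint
#' NNLS (weights from inverse row norms) until the active global component
#' set is stable and no larger than `max_components`, or the relative
#' objective change drops below `tol` (cap `max_iter` iterations). The
#' global restriction to a small set of shared T2 components is what
#' distinguishes this estimate from the voxelwise NNLS map.
#'
#' @inheritParams fit_mwf_nnls
#' @param sparsity_weight dimensionless penalty weight lambda, applied in
#'   its hard-threshold limit: a global component is dropped when its row
#'   norm falls below `lambda` times the largest row norm (equivalently,
#'   when its inverse-row-norm weight exceeds the budget). `0` reduces to
#'   unregularized voxelwise NNLS.
#' @param max_components maximum size of the global T2 support.
#' @param max_iter,tol reweighting iteration cap and relative-objective
#'   tolerance.
#' @return A [volume_map] with role `"MWF_SPIJN"`; attribute `fit` carries
#'   the global support (T2 values, ms), convergence flag and iterations.
#' @export
fit_mwf_spijn <- function(series, grid, params, sparsity_weight = 0.02,
                          max_components = 6, max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(series, "echo_series"), inherits(grid, "t2_grid"),
            inherits(params, "epg_params"))
  idx <- which(series$mask)
  if (length(idx) < 10) stop("SPIJN needs at least 10 masked voxels",
                             call. = FALSE)
  d4 <- dim(series$data)
  B <- matrix(aperm(series$data, c(4, 1, 2, 3)), nrow = d4[4])[, idx,
                                                               drop = FALSE]
  A <- build_decay_basis(grid, params)
  res <- cpp_spijn(B, A, sparsity_weight, as.integer(max_components),
                   as.integer(max_iter), tol)
  win <- grid$t2_values <= grid$myelin_window[2]
  tot <- colSums(res$amplitudes)
  mwf <- ifelse(tot > 0, colSums(res$amplitudes[win, , drop = FALSE]) / tot,
                NA_real_)
  out <- array(NaN, d4[1:3])
  out[idx] <- mwf
  map <- volume_map(out, affine = series$affine, role = "MWF_SPIJN")
  attr(map, "fit") <- list(support_t2 = grid$t2_values[res$support + 1L],
                           converged = res$converged,
                           iterations = res$iterations)
  map
}
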