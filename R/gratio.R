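# Aggregate g-ratio modelling: conversion of each myelin-sensitive measure
# to a myelin volume fraction (hydration model for MWF, calibrated linear
# scaling for the MT measures, identity for MTV), axonal volume fractions
# from NODDI signal fractions, voxelwise g = sqrt(AVF / (AVF + MVF)), and
# the splenium-based cohort calibration of the linear scaling factors.

#' Four-compartment hydration model constants
#'
#' MR-visible (aqueous) volume ratios of the myelin and non-myelin
#' compartments used to scale MWF into a myelin volume fraction.
#'
#' @param kappa_my myelin compartment water ratio, default 0.36.
#' @param kappa_nm non-myelin compartment water ratio, default 0.86.
#' @return A `hydration_model` object.
#' @export
hydration_model <- function(kappa_my = 0.36, kappa_nm = 0.86) {
  if (!(kappa_my > 0 && kappa_my < kappa_nm && kappa_nm <= 1))
    stop("need 0 < kappa_my < kappa_nm <= 1", call. = FALSE)
  structure(list(kappa_my = kappa_my, kappa_nm = kappa_nm),
            class = "hydration_model")
}

mvf_from_mwf_values <- function(mwf, model) {
  mwf * model$kappa_nm / (mwf * (model$kappa_nm - model$kappa_my) +
                            model$kappa_my)
}

mwf_from_mvf_values <- function(mvf, model) {
  mvf * model$kappa_my / (model$kappa_nm -
                            mvf * (model$kappa_nm - model$kappa_my))
}

#' Myelin volume fraction from myelin water fraction
#'
#' `MVF = MWF k_nm / (MWF (k_nm - k_my) + k_my)`: monotone increasing,
#' maps [0, 1] onto [0, 1] and fixes 0 and 1. With the default constants,
#' MWF = 0.080 gives MVF = 0.172 and MWF = 0.041 gives MVF = 0.093.
#'
#' @param mwf [volume_map] (or array/scalar) of MWF values in [0, 1].
#' @param model a [hydration_model].
#' @return same shape as `mwf`, role `"MVF"` for volume maps.
#' @export
mvf_from_mwf <- function(mwf, model = hydration_model()) {
  stopifnot(inherits(model, "hydration_model"))
  v <- vol_values(mwf)
  check_fraction(v, "mwf")
  out <- mvf_from_mwf_values(v, model)
  if (is_volume_map(mwf)) vol_like(mwf, out, role = "MVF") else out
}

#' Myelin water fraction from myelin volume fraction
#'
#' Analytic inverse of [mvf_from_mwf()]; round trips agree to 1e-12.
#'
#' @param mvf [volume_map] (or array/scalar) of MVF values in [0, 1].
#' @inheritParams mvf_from_mwf
#' @return same shape as `mvf`.
#' @export
mwf_from_mvf <- function(mvf, model = hydration_model()) {
  stopifnot(inherits(model, "hydration_model"))
  v <- vol_values(mvf)
  check_fraction(v, "mvf")
  out <- mwf_from_mvf_values(v, model)
  if (is_volume_map(mvf)) vol_like(mvf, out, role = "MWF_true") else out
}

check_fraction <- function(v, what) {
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Linear myelin volume fraction scaling
#'
#' `MVF = alpha x`, clipped to [0, 1] with the clip count recorded; used
#' for the MT-based measures (MTsat, ihMTR) after calibration of `alpha`.
#'
#' @param x [volume_map] or array of the myelin-sensitive measure.
#' @param alpha positive scaling factor.
#' @return same shape as `x`, role `"MVF"` for volume maps; attribute `qc`
#'   holds the clip count.
#' @export
mvf_linear <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive scalar", call. = FALSE)
  v <- vol_values(x) * alpha
  n_clip <- sum(v < 0 | v > 1, na.rm = TRUE)
  v <- pmin(pmax(v, 0), 1)
  out <- if (is_volume_map(x)) vol_like(x, array(v, dim(vol_values(x))),
                                        role = "MVF") else v
  attr(out, "qc") <- list(n_clipped = n_clip, alpha = alpha)
  out
}

#' Myelin volume fraction from macromolecular tissue volume
#'
#' MTV is used directly as a surrogate for MVF (identity with a role
#' change; the input is never mutated).
#'
#' @param mtv [volume_map] or array of MTV fractions in [0, 1].
#' @return copy with role `"MVF"`.
#' @export
mvf_from_mtv <- function(mtv) {
  v <- vol_values(mtv)
  check_fraction(v, "mtv")
  if (is_volume_map(mtv)) vol_like(mtv, v + 0, role = "MVF") else v + 0
}

#' Axonal volume fraction from NODDI signal fractions
#'
#' `AVF = (1 - MVF - NMVF) (1 - v_iso) v_ic`; with `nmvf = 0` this is the
#' primary model, and a nonzero non-myelin macromolecular volume fraction
#' gives the extended form. Voxels with `MVF + NMVF > 1` are invalid and
#' counted.
#'
#' @param mvf [volume_map] or array of myelin volume fractions.
#' @param fractions a `noddi_fractions` object (or list with `v_ic`,
#'   `v_iso`).
#' @param nmvf non-myelin macromolecular map or scalar, default 0.
#' @return same shape as `mvf`, role `"AVF"`.
#' @export
compute_avf <- function(mvf, fractions, nmvf = 0) {
  m <- vol_values(mvf)
  vic <- vol_values(fractions$v_ic)
  viso <- vol_values(fractions$v_iso)
  nm <- if (length(nmvf) == 1) rep(vol_values(nmvf), length(m))
        else vol_values(nmvf)
  if (!is.null(dim(m))) dim(nm) <- dim(m)
  check_fraction(vic, "v_ic"); check_fraction(viso, "v_iso")
  check_fraction(nm, "nmvf")
  avf <- (1 - m - nm) * (1 - viso) * vic
  over <- (m + nm) > 1 + 1e-12
  avf[over] <- NaN
  out <- if (is_volume_map(mvf)) vol_like(mvf, avf, role = "AVF") else avf
  attr(out, "qc") <- list(n_invalid = sum(over, na.rm = TRUE))
  out
}

#' Aggregate g-ratio
#'
#' `g = sqrt(AVF / (AVF + MVF))`: 1 for unmyelinated voxels (MVF = 0,
#' AVF > 0), strictly decreasing in MVF. Voxels with MVF = AVF = 0 are
#' invalid (NaN) and counted.
#'
#' @param mvf,avf [volume_map]s or arrays of volume fractions (>= 0).
#' @return same shape, role `"g"`.
#' @export
compute_gratio <- function(mvf, avf) {
  m <- vol_values(mvf)
  a <- vol_values(avf)
  check_same_grid(m, a)
  if (any(m < -1e-12, na.rm = TRUE) || any(a < -1e-12, na.rm = TRUE))
    stop("mvf and avf must be nonnegative", call. = FALSE)
  tot <- a + m
  g <- sqrt(a / tot)
  g[tot <= 0] <- NaN
  out <- if (is_volume_map(mvf)) vol_like(mvf, g, role = "g", units = "")
         else g
  attr(out, "qc") <- list(n_invalid = sum(tot <= 0, na.rm = TRUE))
  out
}

#' Calibrate a linear MVF scaling factor on a healthy cohort
#'
#' Finds the unique `alpha` such that the cohort-mean splenium g-ratio --
#' voxelwise g from `MVF = alpha x` and the NODDI axonal model, averaged
#' over splenium voxels per subject, then over subjects -- equals
#' `g_target`. The cohort-mean is strictly decreasing in `alpha`, so the
#' root is found by bisection on `[0, alpha_max]` (with `alpha_max` the
#' value at which the largest splenium measure reaches MVF = 1) to
#' `|F(alpha) - g_target| < 1e-8`.
#'
#' @param x_maps list (one per calibration subject) of myelin-sensitive
#'   measure maps.
#' @param fractions list of `noddi_fractions`, parallel to `x_maps`.
#' @param splenium_masks list of logical masks, parallel to `x_maps`.
#' @param g_target target cohort-mean splenium g-ratio in (0, 1),
#'   default 0.7.
#' @return the calibrated scaling factor `alpha`.
#' @export
calibrate_alpha <- function(x_maps, fractions, splenium_masks,
                            g_target = 0.7) {
  if (g_target <= 0 || g_target >= 1)
    stop("g_target must lie in (0, 1)", call. = FALSE)
  ns <- length(x_maps)
  stopifnot(ns >= 1, length(fractions) == ns,
            length(splenium_masks) == ns)
  vox <- vector("list", ns)
  for (s in seq_len(ns)) {
    m <- as_mask(splenium_masks[[s]])
    if (!any(m)) stop("empty splenium mask in calibration subject ", s,
                      call. = FALSE)
    x <- vol_values(x_maps[[s]])[m]
    vic <- vol_values(fractions[[s]]$v_ic)[m]
    viso <- vol_values(fractions[[s]]$v_iso)[m]
    ok <- is.finite(x) & is.finite(vic) & is.finite(viso)
    if (!any(ok)) stop("no valid splenium voxels in subject ", s,
                       call. = FALSE)
    vox[[s]] <- list(x = x[ok], vic = vic[ok], viso = viso[ok])
  }
  cohort_g <- function(alpha) {
    mean(vapply(vox, function(v) {
      mvf <- pmin(alpha * v$x, 1)
      avf <- (1 - mvf) * (1 - v$viso) * v$vic
      g <- sqrt(avf / (avf + mvf))
      mean(g[is.finite(g)])
    }, 0))
  }
  xmax <- max(vapply(vox, function(v) max(v$x), 0))
  if (xmax <= 0) stop("all splenium measures are zero; cannot calibrate",
                      call. = FALSE)
  alpha_max <- 1 / xmax
  f_lo <- 1 # alpha -> 0 gives g -> 1
  f_hi <- cohort_g(alpha_max)
  if (g_target >= f_lo || g_target < f_hi)
    stop(sprintf(paste0("g_target %.3f outside the attainable range ",
                        "(%.4f, 1)"), g_target, f_hi), call. = FALSE)
  lo <- 0; hi <- alpha_max
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    fm <- cohort_g(mid)
    if (abs(fm - g_target) < 1e-8) return(mid)
    if (fm > g_target) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

#' Full g-ratio pipeline for one subject and one myelin measure
#'
#' Dispatches to the correct MVF model -- the hydration model for the two
#' MWF variants, the calibrated linear scaling for ihMTR and MTsat, the
#' identity for MTV -- then computes AVF from the NODDI fractions and the
#' voxelwise g-ratio map.
#'
#' @param maps named list of subject maps; must contain the map named by
#'   `method` (`mwf_nnls`, `mwf_spijn`, `ihmtr`, `mtsat`, `mtv`).
#' @param fractions a `noddi_fractions` object for the subject.
#' @param method which myelin-sensitive measure to use.
#' @param alpha calibrated scaling factor (required for `ihmtr`/`mtsat`).
#' @param model a [hydration_model] (used by the MWF methods).
#' @param nmvf non-myelin macromolecular map or scalar, default 0.
#' @return A `gratio_maps` list: `mvf`, `avf`, `g` volume maps plus
#'   `provenance` (method, constants, alpha, timestamp).
#' @export
run_gratio_pipeline <- function(maps, fractions,
                                method = c("mwf_nnls", "mwf_spijn",
                                           "ihmtr", "mtsat", "mtv"),
                                alpha = NULL, model = hydration_model(),
                                nmvf = 0) {
  method <- match.arg(method)
  x <- maps[[method]]
  if (is.null(x)) stop("maps must contain an entry named '", method, "'",
                       call. = FALSE)
  mvf <- switch(method,
    mwf_nnls = , mwf_spijn = mvf_from_mwf(clip_unit(x), model),
    ihmtr = , mtsat = {
      if (is.null(alpha))
        stop("methods ihmtr/mtsat need a calibrated alpha ",
             "(see calibrate_alpha)", call. = FALSE)
      mvf_linear(x, alpha)
    },
    mtv = mvf_from_mtv(x))
  avf <- compute_avf(mvf, fractions, nmvf = nmvf)
  g <- compute_gratio(mvf, avf)
  structure(list(mvf = mvf, avf = avf, g = g,
                 provenance = list(method = method,
                                   kappa_my = model$kappa_my,
                                   kappa_nm = model$kappa_nm,
                                   alpha = alpha,
                                   nmvf = if (length(nmvf) == 1) nmvf
                                          else "map",
                                   date = format(Sys.time(),
                                                 "%Y-%m-%dT%H:%M:%S"))),
            class = "gratio_maps")
}

# clamp tiny numerical excursions outside [0, 1] (keeps NaN)
clip_unit <- function(x) {
  v <- vol_values(x)
  v <- pmin(pmax(v, 0), 1)
  dim(v) <- dim(vol_values(x))
  if (is_volume_map(x)) vol_like(x, v) else v
}
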