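# Magnetization-transfer parameter maps: inhomogeneous MT ratio (ihMTR)
# from the four MT-weighted volumes plus reference, MT saturation (MTsat),
# R1 and apparent amplitude from the T1-/PD-/MT-weighted gradient-echo
# triple, reference-region proton density calibration, and the
# macromolecular tissue volume MTV = 1 - PD/100.

#' Inhomogeneous magnetization transfer ratio
#'
#' `ihMTR = (S+ + S- - S_dualA - S_dualB) / (2 M0)` (default), or, in the
#' `"single-m0"` dialect, the same difference divided by `M0` only. Values
#' are not clamped: negative voxels are permitted and counted in the QC
#' attribute. Voxels with `M0 <= 0` are invalid (NaN).
#'
#' @param quad an `mt_quadruple` (see [simulate_mt_quadruple()]) or a named
#'   list of five maps `s_plus`, `s_minus`, `s_dual_a`, `s_dual_b`, `m0`.
#' @param dialect `"dual-m0"` (divide by `2 M0`, default) or
#'   `"single-m0"`.
#' @return A [volume_map] with role `"ihMTR"`; attribute `qc` counts
#'   negative and invalid voxels.
#' @export
compute_ihmtr <- function(quad, dialect = c("dual-m0", "single-m0")) {
  dialect <- match.arg(dialect)
  need <- c("s_plus", "s_minus", "s_dual_a", "s_dual_b", "m0")
  if (!all(need %in% names(quad)))
    stop("quadruple must provide ", paste(need, collapse = ", "),
         call. = FALSE)
  arrs <- lapply(quad[need], vol_values)
  do.call(check_same_grid, arrs)
  denom <- if (dialect == "dual-m0") 2 * arrs$m0 else arrs$m0
  num <- arrs$s_plus + arrs$s_minus - arrs$s_dual_a - arrs$s_dual_b
  out <- num / denom
  out[!is.finite(out) | arrs$m0 <= 0] <- NaN
  aff <- if (is_volume_map(quad$m0)) quad$m0$affine else diag(4)
  map <- volume_map(out, affine = aff, role = "ihMTR")
  attr(map, "qc") <- list(n_negative = sum(out < 0, na.rm = TRUE),
                          n_invalid = sum(!is.finite(out)),
                          dialect = dialect)
  map
}

#' MTsat, R1 and apparent amplitude from the gradient-echo triple
#'
#' Rational small-flip-angle estimators from the dual-angle (T1w, PDw)
#' pair, then the per-excitation MT saturation from the MTw volume:
#' `delta = (A alpha_MT / S_MT - 1) R1 TR_MT - alpha_MT^2 / 2` (radians
#' squared), reported as percent (x100). B1 is assumed uniform (no
#' model-based B1 correction).
#'
#' @param inputs an `mtsat_inputs` object: maps `s_t1w`, `s_pdw`, `s_mtw`
#'   plus `flip_angles` (degrees) and `repetition_times` (ms), ordered
#'   (T1w, PDw, MTw).
#' @return list of three [volume_map]s: `mtsat` (role `"MTsat"`, percent),
#'   `r1` (role `"R1"`, 1/s), `a_app` (role `"A_app"`).
#' @export
fit_mtsat <- function(inputs) {
  need <- c("s_t1w", "s_pdw", "s_mtw")
  if (!all(need %in% names(inputs)))
    stop("inputs must provide ", paste(need, collapse = ", "),
         call. = FALSE)
  fa <- inputs$flip_angles
  tr <- inputs$repetition_times
  if (length(fa) != 3 || length(tr) != 3)
    stop("need flip_angles and repetition_times triples (T1w, PDw, MTw)",
         call. = FALSE)
  if (fa[1] == fa[2])
    stop("T1w and PDw flip angles must differ", call. = FALSE)
  st1 <- vol_values(inputs$s_t1w)
  spd <- vol_values(inputs$s_pdw)
  smt <- vol_values(inputs$s_mtw)
  check_same_grid(st1, spd, smt)
  a <- fa * pi / 180
  trs <- tr / 1000 # s
  # rational dual-angle estimators
  r1 <- 0.5 * (st1 * a[1] / trs[1] - spd * a[2] / trs[2]) /
    (spd / a[2] - st1 / a[1])
  a_app <- spd * st1 * (trs[2] * a[1] / a[2] - trs[1] * a[2] / a[1]) /
    (st1 * trs[2] * a[1] - spd * trs[1] * a[2])
  delta <- (a_app * a[3] / smt - 1) * r1 * trs[3] - a[3]^2 / 2
  bad <- !is.finite(r1) | !is.finite(a_app) | !is.finite(delta) |
    spd <= 0 | st1 <= 0 | smt <= 0
  r1[bad] <- NaN; a_app[bad] <- NaN; delta[bad] <- NaN
  aff <- if (is_volume_map(inputs$s_pdw)) inputs$s_pdw$affine else diag(4)
  list(mtsat = volume_map(100 * delta, aff, role = "MTsat", units = "%"),
       r1 = volume_map(r1, aff, role = "R1", units = "1/s"),
       a_app = volume_map(a_app, aff, role = "A_app"))
}

#' Proton-density calibration specification
#'
#' @param mode `"csf100"` (CSF mean set to 100%, the primary convention) or
#'   `"wm69"` (whole-brain WM mean set to 69%).
#' @return A `pd_calibration` object with the reference mask role and
#'   value.
#' @export
pd_calibration <- function(mode = c("csf100", "wm69")) {
  mode <- match.arg(mode)
  structure(list(mode = mode,
                 reference_mask_role = if (mode == "csf100") "CSF" else "WM",
                 reference_value = if (mode == "csf100") 100 else 69),
            class = "pd_calibration")
}

#' Calibrate apparent amplitude into percent proton density
#'
#' `PD = A_app * reference_value / mean(A_app over the reference mask)`,
#' clipped to [0, 110] with the clip count recorded. Calibrating an
#' already-calibrated map is a no-op.
#'
#' @param a_app [volume_map] of apparent amplitudes.
#' @param cal a [pd_calibration].
#' @param masks named list of masks containing the reference role
#'   (`CSF` or `WM`).
#' @return A [volume_map] with role `"PD"` (percent); attribute `qc`
#'   carries the scale factor and clip count.
#' @export
calibrate_pd <- function(a_app, cal = pd_calibration(), masks) {
  stopifnot(inherits(cal, "pd_calibration"))
  ref <- masks[[cal$reference_mask_role]]
  if (is.null(ref) || !any(as_mask(ref)))
    stop("reference mask ", cal$reference_mask_role,
         " is missing or empty", call. = FALSE)
  vals <- vol_values(a_app)
  check_same_grid(vals, as_mask(ref))
  refvals <- vals[as_mask(ref)]
  refmean <- mean(refvals[is.finite(refvals)])
  if (!is.finite(refmean) || refmean <= 0)
    stop("non-positive mean amplitude in the reference region",
         call. = FALSE)
  pd <- vals * (cal$reference_value / refmean)
  n_clip <- sum(pd < 0 | pd > 110, na.rm = TRUE)
  pd <- pmin(pmax(pd, 0), 110)
  dim(pd) <- dim(vals)
  aff <- if (is_volume_map(a_app)) a_app$affine else diag(4)
  map <- volume_map(pd, aff, role = "PD", units = "%")
  attr(map, "qc") <- list(scale = cal$reference_value / refmean,
                          n_clipped = n_clip, mode = cal$mode)
  map
}

#' Macromolecular tissue volume from proton density
#'
#' `MTV = 1 - PD/100`, clipped to [0, 1]; all non-water protons are taken
#' to be macromolecules.
#'
#' @param pd [volume_map] of proton density in percent.
#' @return A [volume_map] with role `"MTV"` (fraction).
#' @export
compute_mtv <- function(pd) {
  vals <- vol_values(pd)
  mtv <- pmin(pmax(1 - vals / 100, 0), 1)
  dim(mtv) <- dim(vals)
  aff <- if (is_volume_map(pd)) pd$affine else diag(4)
  volume_map(mtv, aff, role = "MTV")
}
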