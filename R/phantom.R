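# Synthetic brain-phantom cohort: healthy and lesioned subjects with
# ground-truth microstructure, plus forward simulators for every acquired
# contrast (multi-echo spin-echo series, MT-weighted quadruple,
# gradient-echo triple, NODDI fractions). Everything is deterministic given
# the seed, and every simulator has an estimator counterpart that recovers
# the truth in the noiseless limit.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Cohort specification for the synthetic phantom
#'
#' The stated world of the simulated study: cohort sizes, grid, lesion load,
#' myelin levels and noise. Defaults emulate a small two-group study on a
#' 48x48x24 voxel grid at 1 mm isotropic resolution, white matter myelin
#' volume fraction around 0.30, lesions of 2-4 mm radius demyelinated by a
#' per-lesion factor in [0.2, 0.9], and Rician noise with a first-echo SNR
#' of 200 (noise_sigma = 0.005).
#'
#' @param n_healthy,n_patients subject counts (>= 1).
#' @param grid_shape integer triple of voxel dimensions.
#' @param lesion_count_per_patient lesions per patient.
#' @param lesion_radius_range lesion radius range in mm.
#' @param noise_sigma relative noise standard deviation (reference-region
#'   signal = 1/SNR); >= 0.
#' @param seed integer master seed; per-subject seeds derive from it.
#' @param voxel_size_mm voxel size triple in mm.
#' @param wm_mvf_mean mean white-matter myelin volume fraction.
#' @param wm_heterogeneity amplitude of the smooth spatial variation of WM
#'   myelin (0 gives homogeneous WM, used by null-calibration experiments).
#' @param subject_sd between-subject SD of the WM myelin level.
#' @param regional_contrast multiplier on the splenium/internal-capsule
#'   myelin offsets (1 = physiological contrast; 0 gives homogeneous WM
#'   for null-calibration experiments).
#' @param lesion_demyelination range of the per-lesion multiplicative myelin
#'   retention factor (1 = no effect, used by null experiments).
#' @param nmvf_lesion non-myelin macromolecular volume fraction added inside
#'   lesions (0 by default: the primary model assumes the macromolecular
#'   pool equals the myelin pool).
#' @param forward_slope linear slope tying simulated ihMTR to the true MVF.
#' @param mtsat_slope linear slope tying the per-excitation MT saturation
#'   delta to the true MVF.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_healthy = 6, n_patients = 6,
                        grid_shape = c(48, 48, 24),
                        lesion_count_per_patient = 3,
                        lesion_radius_range = c(2, 4),
                        noise_sigma = 0.005, seed = 1,
                        voxel_size_mm = c(1, 1, 1),
                        wm_mvf_mean = 0.30, wm_heterogeneity = 0.015,
                        subject_sd = 0.01, regional_contrast = 1,
                        lesion_demyelination = c(0.2, 0.9),
                        nmvf_lesion = 0,
                        forward_slope = 0.2, mtsat_slope = 0.12) {
  stopifnot(n_healthy >= 1, n_patients >= 1, length(grid_shape) == 3,
            all(grid_shape >= 8), lesion_count_per_patient >= 0,
            noise_sigma >= 0, forward_slope > 0, mtsat_slope > 0)
  if (diff(lesion_radius_range) < 0 || lesion_radius_range[1] <= 0)
    stop("invalid lesion radius range", call. = FALSE)
  structure(list(n_healthy = as.integer(n_healthy),
                 n_patients = as.integer(n_patients),
                 grid_shape = as.integer(grid_shape),
                 lesion_count_per_patient =
                   as.integer(lesion_count_per_patient),
                 lesion_radius_range = lesion_radius_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 voxel_size_mm = voxel_size_mm,
                 wm_mvf_mean = wm_mvf_mean,
                 wm_heterogeneity = wm_heterogeneity,
                 subject_sd = subject_sd,
                 regional_contrast = regional_contrast,
                 lesion_demyelination = lesion_demyelination,
                 nmvf_lesion = nmvf_lesion,
                 forward_slope = forward_slope,
                 mtsat_slope = mtsat_slope),
            class = "cohort_spec")
}

# normalized [-1, 1] coordinate arrays for a grid
phantom_coords <- function(gs) {
  ax <- function(n) (seq_len(n) - (n + 1) / 2) / (n / 2)
  list(u = array(rep(ax(gs[1]), times = gs[2] * gs[3]), gs),
       v = array(rep(rep(ax(gs[2]), each = gs[1]), times = gs[3]), gs),
       w = array(rep(ax(gs[3]), each = gs[1] * gs[2]), gs))
}

phantom_regions <- function(gs) {
  co <- phantom_coords(gs)
  u <- co$u; v <- co$v; w <- co$w
  rho2 <- (u / 0.92)^2 + (v / 0.92)^2 + (w / 0.88)^2
  brain <- rho2 <= 1
  vent <- ((u / 0.22)^2 + ((v - 0.05) / 0.30)^2 +
             ((w + 0.10) / 0.28)^2) <= 1
  gm <- brain & rho2 > 0.78^2
  wm <- brain & rho2 <= 0.78^2 & !vent
  cc <- wm & abs(u) <= 0.20 & abs(v) <= 0.62 & w >= 0.12 & w <= 0.50
  splenium <- cc & v <= -0.30
  cr <- wm & abs(u) >= 0.22 & abs(u) <= 0.45 & abs(v) <= 0.40 &
    w >= 0.35 & w <= 0.55
  ic <- wm & abs(u) >= 0.20 & abs(u) <= 0.40 & v >= -0.15 & v <= 0.25 &
    w >= -0.30 & w <= -0.05
  regions <- list(brain = brain, CSF = vent & brain, GM = gm, WM = wm,
                  CC = cc, splenium = splenium, CR = cr, IC = ic)
  for (r in c("CSF", "GM", "WM", "CC", "splenium", "CR", "IC")) {
    m <- regions[[r]]
    if (!any(m)) stop("grid ", paste(gs, collapse = "x"),
                      " too small: region ", r, " is empty", call. = FALSE)
    ext <- apply(which(m, arr.ind = TRUE), 2, function(i) diff(range(i)) + 1)
    if (min(ext) < 3 && r %in% c("WM", "CC", "splenium"))
      stop("grid too small: region ", r, " is under 3 voxels across",
           call. = FALSE)
  }
  c(regions, co)
}

#' Build one synthetic subject's ground truth and VOI masks
#'
#' Generates an ellipsoidal brain with CSF ventricles, a cortical GM shell,
#' WM, a midline corpus-callosum slab whose posterior third is the splenium,
#' two further atlas-like WM sub-regions (corona radiata, internal capsule),
#' and -- for patients -- spherical lesions with smooth one-voxel sigmoid
#' edges placed inside WM, each demyelinated by its own factor. Ground-truth
#' myelin, axonal, non-myelin-macromolecular, myelin water and NODDI
#' fraction maps are returned together with the VOI masks. Deterministic
#' given `seed`.
#'
#' @param spec a [cohort_spec].
#' @param subject_kind `"healthy"` or `"patient"`.
#' @param seed integer seed for this subject.
#' @return list with `truth` (class `phantom_truth`) and `vois` (named list
#'   of logical masks plus `lesion_probability`).
#' @export
build_phantom <- function(spec, subject_kind = c("healthy", "patient"),
                          seed = spec$seed) {
  subject_kind <- match.arg(subject_kind)
  gs <- spec$grid_shape
  reg <- phantom_regions(gs)
  with_local_seed(seed, {
    model <- hydration_model()
    wm <- reg$WM; gm <- reg$GM; csf <- reg$CSF
    # smooth in-WM heterogeneity with subject-specific phases
    ph <- runif(3, 0, 2 * pi)
    het <- spec$wm_heterogeneity *
      (sin(2 * pi * 1.5 * (reg$u + 1) / 2 + ph[1]) *
         cos(2 * pi * (reg$v + 1) / 2 + ph[2]) +
         0.5 * sin(2 * pi * 2 * (reg$w + 1) / 2 + ph[3]))
    subj_shift <- rnorm(1, 0, spec$subject_sd)
    mvf <- array(0, gs)
    mvf[wm] <- spec$wm_mvf_mean + subj_shift + het[wm]
    rc <- spec$regional_contrast %||% 1
    mvf[reg$splenium] <- mvf[reg$splenium] + 0.03 * rc
    mvf[reg$IC] <- mvf[reg$IC] + 0.02 * rc
    mvf[gm] <- 0.10 + 0.5 * subj_shift
    mvf[csf] <- 0
    mvf <- pmin(pmax(mvf, 0), 0.9)
    dim(mvf) <- gs

    # lesions (patients only): spheres with 1-voxel sigmoid edges in WM
    omega <- array(0, gs)
    lesion_factors <- numeric(0)
    if (subject_kind == "patient" && spec$lesion_count_per_patient > 0) {
      rmax <- spec$lesion_radius_range[2]
      # candidate centers per integer radius: erode WM so lesions stay
      # fully inside it
      cands <- list()
      em <- wm
      for (k in seq_len(ceiling(rmax))) {
        em <- erode_mask(em)
        cands[[k]] <- which(em, arr.ind = TRUE)
      }
      if (nrow(cands[[ceiling(spec$lesion_radius_range[1])]]) == 0)
        stop("grid too small for requested lesion radius", call. = FALSE)
      centers <- matrix(numeric(0), 0, 3)
      radii <- numeric(0)
      attempts <- 0
      while (length(radii) < spec$lesion_count_per_patient) {
        attempts <- attempts + 1
        if (attempts > 2000)
          stop("could not place ", spec$lesion_count_per_patient,
               " disjoint lesions on this grid", call. = FALSE)
        r <- runif(1, spec$lesion_radius_range[1],
                   spec$lesion_radius_range[2])
        cand <- cands[[ceiling(r)]]
        if (nrow(cand) == 0) next
        ctr <- cand[sample.int(nrow(cand), 1), ]
        if (nrow(centers) > 0) {
          dd <- sqrt(colSums((t(centers) - ctr)^2))
          if (any(dd <= radii + r + 1.5)) next
        }
        centers <- rbind(centers, ctr)
        radii <- c(radii, r)
      }
      lesion_factors <- runif(length(radii), spec$lesion_demyelination[1],
                              spec$lesion_demyelination[2])
      vx <- spec$voxel_size_mm
      for (i in seq_along(radii)) {
        d <- sqrt((vx[1] * (reg$u * gs[1] / 2 - (centers[i, 1] - (gs[1] + 1) / 2)))^2 +
                  (vx[2] * (reg$v * gs[2] / 2 - (centers[i, 2] - (gs[2] + 1) / 2)))^2 +
                  (vx[3] * (reg$w * gs[3] / 2 - (centers[i, 3] - (gs[3] + 1) / 2)))^2)
        wi <- 1 / (1 + exp((d - radii[i]) / 0.5))
        wi[!wm] <- 0 # lesions only inside WM
        mvf <- mvf * (1 - (1 - lesion_factors[i]) * wi)
        omega <- pmax(omega, wi)
      }
      dim(mvf) <- gs
      dim(omega) <- gs
    }
    lesion <- omega > 0.5

    v_ic <- array(0, gs)
    v_ic[wm] <- 0.65
    v_ic[gm] <- 0.45
    v_ic[csf] <- 0.02
    v_ic <- v_ic * (1 - 0.45 * omega) # axonal loss inside lesions
    v_iso <- array(0, gs)
    v_iso[wm] <- 0.04
    v_iso[gm] <- 0.12
    v_iso[csf] <- 0.98
    nmvf <- spec$nmvf_lesion * omega
    dim(v_ic) <- gs; dim(nmvf) <- gs

    mwf <- mwf_from_mvf_values(mvf, model)
    avf <- (1 - mvf - nmvf) * (1 - v_iso) * v_ic

    labels <- array(0L, gs)
    labels[csf] <- 1L
    labels[gm] <- 2L
    labels[wm] <- 3L
    labels[lesion] <- 4L

    truth <- structure(list(tissue_labels = labels, mvf_true = mvf,
                            avf_true = avf, nmvf_true = nmvf,
                            mwf_true = mwf, v_ic_true = v_ic,
                            v_iso_true = v_iso,
                            voxel_size_mm = spec$voxel_size_mm,
                            lesion_factors = lesion_factors,
                            grid_shape = gs),
                       class = "phantom_truth")

    excl <- lesion
    vois <- list(WM = wm & !excl, GM = gm & !excl, CSF = csf & !excl,
                 CC = reg$CC & !excl, CR = reg$CR & !excl,
                 IC = reg$IC & !excl, splenium = reg$splenium & !excl,
                 lesion = lesion,
                 perilesion = make_perilesion(lesion, wm & !excl),
                 lesion_shell = make_lesion_shell(lesion),
                 brain = reg$brain, lesion_probability = omega)
    list(truth = truth, vois = vois)
  })
}

# add complex Gaussian noise on two quadrature channels, take the magnitude
rician <- function(x, sigma) {
  if (sigma <= 0) return(x)
  sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
}

# compartment water amplitudes implied by the truth maps; amplitudes sum to
# the voxel water content and the short-T2 share equals mwf_true
truth_water <- function(truth) {
  W <- 1 - truth$mvf_true - truth$nmvf_true
  W[truth$tissue_labels == 0L] <- 0
  W
}

#' Simulate a multi-echo spin-echo (GRASE-like) series
#'
#' Per voxel the signal is a sum over three water compartments (myelin
#' water T2 = 20 ms, intra/extracellular water T2 = 80 ms, free water
#' T2 = 2000 ms) of amplitude times the EPG decay curve at the stated
#' refocusing flip angle. Amplitudes are set so the myelin-water share
#' equals `mwf_true` and their sum equals the voxel water content. Rician
#' noise: zero-mean Gaussian on two quadrature channels, then magnitude;
#' sigma is `noise_sigma` times the mean noiseless first-echo WM signal.
#'
#' @param truth a `phantom_truth`.
#' @param n_echoes number of echoes (>= 2), default 48.
#' @param echo_spacing echo spacing in ms, default 8.
#' @param refocusing_flip refocusing flip in degrees (0, 180], default 165
#'   so that stimulated-echo correction is exercised.
#' @param noise_sigma relative noise SD (0 = noiseless).
#' @param seed integer seed.
#' @return An [echo_series] masked to the brain.
#' @export
simulate_echo_series <- function(truth, n_echoes = 48, echo_spacing = 8,
                                 refocusing_flip = 165, noise_sigma = 0,
                                 seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (n_echoes < 2) stop("need at least 2 echoes", call. = FALSE)
  if (echo_spacing <= 0) stop("echo spacing must be > 0", call. = FALSE)
  if (refocusing_flip <= 0 || refocusing_flip > 180)
    stop("refocusing flip must be in (0, 180]", call. = FALSE)
  gs <- truth$grid_shape
  W <- truth_water(truth)
  mwf <- truth$mwf_true
  viso <- truth$v_iso_true
  amps <- cbind(my = as.vector(W * mwf),
                ie = as.vector(W * (1 - mwf) * (1 - viso)),
                fw = as.vector(W * (1 - mwf) * viso))
  pars <- epg_params(refocusing_flip, 1000, echo_spacing, n_echoes)
  curves <- rbind(epg_decay_curve(20, pars), epg_decay_curve(80, pars),
                  epg_decay_curve(2000, pars))
  S <- amps %*% curves # voxels x echoes
  wm <- truth$tissue_labels == 3L
  sigma <- noise_sigma * mean(S[as.vector(wm), 1])
  data <- with_local_seed(seed, {
    if (sigma > 0) array(rician(S, sigma), c(gs, n_echoes))
    else array(S, c(gs, n_echoes))
  })
  echo_series(data, echo_times = seq_len(n_echoes) * echo_spacing,
              mask = array(truth$tissue_labels > 0L, gs),
              affine = diag(c(truth$voxel_size_mm, 1)))
}

#' Simulate the four MT-weighted volumes plus reference
#'
#' Forward model: the reference `m0` is the tissue water content; the
#' single-offset images are attenuated by a conventional-MT term
#' proportional to the total macromolecular fraction, and the dual-offset
#' images additionally by `forward_slope * mvf_true * m0`, so that the
#' constructed ihMTR `(S+ + S- - S_dualA - S_dualB) / (2 m0)` equals
#' `forward_slope * mvf_true` exactly in the noiseless case (the assumed
#' linear ihMTR-myelin relation, by construction).
#'
#' @param truth a `phantom_truth`.
#' @param forward_slope linear slope (> 0); simulated ihMTR must stay in
#'   [0, 0.2].
#' @param noise_sigma relative noise SD.
#' @param seed integer seed.
#' @return An `mt_quadruple`: list of five [volume_map]s (`s_plus`,
#'   `s_minus`, `s_dual_a`, `s_dual_b`, `m0`).
#' @export
simulate_mt_quadruple <- function(truth, forward_slope = 0.2,
                                  noise_sigma = 0, seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (forward_slope <= 0) stop("forward_slope must be > 0", call. = FALSE)
  if (forward_slope * max(truth$mvf_true) > 0.2)
    stop("forward_slope too large: simulated ihMTR would exceed 0.2",
         call. = FALSE)
  W <- truth_water(truth)
  mm <- truth$mvf_true + truth$nmvf_true
  c_mt <- 0.3 # conventional MT attenuation per unit macromolecular fraction
  s_single <- W * (1 - c_mt * mm)
  s_dual <- s_single - W * forward_slope * truth$mvf_true
  if (any(s_dual < 0))
    stop("forward_slope produces negative dual-offset intensities",
         call. = FALSE)
  wm <- truth$tissue_labels == 3L
  sigma <- noise_sigma * mean(W[wm])
  aff <- diag(c(truth$voxel_size_mm, 1))
  gs <- truth$grid_shape
  vols <- with_local_seed(seed, {
    lapply(list(s_plus = s_single, s_minus = s_single, s_dual_a = s_dual,
                s_dual_b = s_dual, m0 = W),
           function(x) array(rician(x, sigma), gs))
  })
  structure(list(s_plus = volume_map(vols$s_plus, aff, "M0"),
                 s_minus = volume_map(vols$s_minus, aff, "M0"),
                 s_dual_a = volume_map(vols$s_dual_a, aff, "M0"),
                 s_dual_b = volume_map(vols$s_dual_b, aff, "M0"),
                 m0 = volume_map(vols$m0, aff, "M0")),
            class = "mt_quadruple")
}

#' Simulate the T1-/PD-/MT-weighted gradient-echo triple
#'
#' Uses the small-flip-angle rational spoiled-gradient-echo signal model
#' `S = A alpha TR R1 / (alpha^2/2 + delta + TR R1)` (delta = 0 for the
#' T1w/PDw volumes), with amplitude `A` equal to the voxel water content and
#' `R1 = 0.25 + 2.4 mvf + 0.2 (1 - v_iso)` (1/s), so the MTsat/R1/A
#' estimators recover the simulated parameters exactly in the noiseless
#' case. `delta_true = mtsat_slope * (mvf_true + nmvf_true)`: the MT
#' saturation responds to the total macromolecular pool, so lesions with
#' elevated non-myelin macromolecules saturate more than their myelin
#' content alone would explain (with the default `nmvf_true = 0` this
#' reduces to a pure myelin proxy).
#'
#' @param truth a `phantom_truth`.
#' @param flip_angles degrees, triple (T1w, PDw, MTw), each < 25.
#' @param repetition_times ms, triple (T1w, PDw, MTw).
#' @param mtsat_slope slope of `delta_true` in `mvf_true`.
#' @param noise_sigma relative noise SD.
#' @param seed integer seed.
#' @return An `mtsat_inputs` object: `s_t1w`, `s_pdw`, `s_mtw` volume maps
#'   plus `flip_angles` and `repetition_times`; attribute `truth` carries
#'   the simulated `delta_true`, `r1_true` and `a_true` maps.
#' @export
simulate_mtsat_inputs <- function(truth, flip_angles = c(20, 6, 6),
                                  repetition_times = c(18, 24, 24),
                                  mtsat_slope = 0.12, noise_sigma = 0,
                                  seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (any(flip_angles >= 90))
    stop("flip angle >= 90 degrees: small-angle model invalid",
         call. = FALSE)
  if (any(flip_angles > 25))
    stop("flip angles must be small (<= 25 degrees)", call. = FALSE)
  A <- truth_water(truth)
  R1 <- 0.25 + 2.4 * truth$mvf_true + 0.2 * (1 - truth$v_iso_true) # 1/s
  delta <- mtsat_slope * (truth$mvf_true + truth$nmvf_true)
  al <- flip_angles * pi / 180
  tr <- repetition_times / 1000 # s
  sig <- function(a, TR, dl) A * a * (TR * R1) / (a^2 / 2 + dl + TR * R1)
  s <- list(s_t1w = sig(al[1], tr[1], 0), s_pdw = sig(al[2], tr[2], 0),
            s_mtw = sig(al[3], tr[3], delta))
  wm <- truth$tissue_labels == 3L
  sigma <- noise_sigma * mean(s$s_pdw[wm])
  gs <- truth$grid_shape
  aff <- diag(c(truth$voxel_size_mm, 1))
  s <- with_local_seed(seed, lapply(s, function(x)
    array(rician(x, sigma), gs)))
  out <- structure(list(s_t1w = volume_map(s$s_t1w, aff, "unknown"),
                        s_pdw = volume_map(s$s_pdw, aff, "unknown"),
                        s_mtw = volume_map(s$s_mtw, aff, "unknown"),
                        flip_angles = flip_angles,
                        repetition_times = repetition_times),
                   class = "mtsat_inputs")
  attr(out, "truth") <- list(delta_true = delta, r1_true = R1, a_true = A)
  out
}

#' Emulate NODDI intracellular and isotropic signal fractions
#'
#' Diffusion model fitting is upstream of this package; its outputs are
#' emulated as the ground-truth fractions plus clipped Gaussian noise.
#' Intracellular fractions are strongly decreased inside lesions by
#' construction of the truth maps.
#'
#' @param truth a `phantom_truth`.
#' @param noise_sigma additive Gaussian SD before clipping to [0, 1].
#' @param seed integer seed.
#' @return A `noddi_fractions` object: `v_ic` and `v_iso` volume maps.
#' @export
simulate_noddi_fractions <- function(truth, noise_sigma = 0, seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  gs <- truth$grid_shape
  aff <- diag(c(truth$voxel_size_mm, 1))
  out <- with_local_seed(seed, {
    jit <- function(x) {
      y <- x + rnorm(length(x), 0, noise_sigma)
      array(pmin(pmax(y, 0), 1), gs)
    }
    list(v_ic = jit(truth$v_ic_true), v_iso = jit(truth$v_iso_true))
  })
  structure(list(v_ic = volume_map(out$v_ic, aff, "v_ic"),
                 v_iso = volume_map(out$v_iso, aff, "v_iso")),
            class = "noddi_fractions")
}

#' Simulate all contrasts for one subject
#'
#' Convenience wrapper: builds the phantom and runs every forward
#' simulator with seeds derived from `subject_seed`.
#'
#' @param spec a [cohort_spec].
#' @param subject_kind `"healthy"` or `"patient"`.
#' @param subject_seed integer seed for this subject.
#' @param id subject identifier string.
#' @param channels which acquisitions to simulate (subset of
#'   `c("echo", "mt", "mtsat", "noddi")`).
#' @param refocusing_flip refocusing flip for the echo series.
#' @return A `phantom_subject` list: `id`, `group`, `truth`, `vois` and the
#'   simulated acquisitions.
#' @export
simulate_subject <- function(spec, subject_kind, subject_seed,
                             id = sprintf("%s%03d", subject_kind,
                                          subject_seed %% 1000L),
                             channels = c("echo", "mt", "mtsat", "noddi"),
                             refocusing_flip = 165) {
  ph <- build_phantom(spec, subject_kind, seed = subject_seed)
  out <- list(id = id, group = subject_kind, truth = ph$truth,
              vois = ph$vois)
  if ("echo" %in% channels)
    out$echo <- simulate_echo_series(ph$truth, noise_sigma =
                                       spec$noise_sigma,
                                     refocusing_flip = refocusing_flip,
                                     seed = subject_seed + 1L)
  if ("mt" %in% channels)
    out$mt_quad <- simulate_mt_quadruple(ph$truth, spec$forward_slope,
                                         spec$noise_sigma,
                                         seed = subject_seed + 2L)
  if ("mtsat" %in% channels)
    out$mtsat_in <- simulate_mtsat_inputs(ph$truth,
                                          mtsat_slope = spec$mtsat_slope,
                                          noise_sigma = spec$noise_sigma,
                                          seed = subject_seed + 3L)
  if ("noddi" %in% channels)
    out$noddi <- simulate_noddi_fractions(ph$truth,
                                          noise_sigma =
                                            spec$noise_sigma / 2,
                                          seed = subject_seed + 4L)
  class(out) <- "phantom_subject"
  out
}

#' Per-subject seeds of a cohort
#' @param spec a [cohort_spec].
#' @return named integer vector, one seed per subject (healthy first).
#' @export
cohort_seeds <- function(spec) {
  n <- spec$n_healthy + spec$n_patients
  seeds <- (spec$seed + 7919L * seq_len(n)) %% 2147483647L
  names(seeds) <- c(sprintf("healthy%02d", seq_len(spec$n_healthy)),
                    sprintf("patient%02d", seq_len(spec$n_patients)))
  seeds
}
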