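# Synthetic cohort generator: geometry, ground-truth invariants, and the
# forward simulators for every acquired contrast.

test_that("phantom geometry, lesions and determinism", {
  spec <- cohort_spec(seed = 5, lesion_count_per_patient = 3,
                      lesion_radius_range = c(2, 3))
  ph <- build_phantom(spec, "patient", seed = 42)
  ph2 <- build_phantom(spec, "patient", seed = 42)
  expect_identical(ph$truth, ph2$truth)

  hp <- build_phantom(spec, "healthy", seed = 42)
  expect_equal(sum(hp$vois$lesion), 0)

  # requested number of disjoint connected lesion components
  expect_equal(max(label_components(ph$vois$lesion)), 3)

  tr <- ph$truth
  for (f in c("mvf_true", "avf_true", "nmvf_true", "mwf_true", "v_ic_true",
              "v_iso_true")) {
    expect_true(all(tr[[f]] >= 0 & tr[[f]] <= 1), info = f)
  }
  expect_true(all(tr$mvf_true + tr$avf_true + tr$nmvf_true <= 1 + 1e-12))
  # axonal construction identity
  expect_equal(tr$avf_true,
               (1 - tr$mvf_true - tr$nmvf_true) * (1 - tr$v_iso_true) *
                 tr$v_ic_true)
  # lesions only inside tissue that was WM
  expect_true(all(tr$tissue_labels[ph$vois$lesion] == 4L))
  expect_false(any(ph$vois$lesion & (tr$tissue_labels == 1L |
                                       tr$tissue_labels == 2L)))
  # non-lesion VOIs exclude lesion voxels
  for (r in c("WM", "GM", "CSF", "CC", "CR", "IC", "splenium"))
    expect_false(any(ph$vois[[r]] & ph$vois$lesion), info = r)

  # sizing error on an inadequate grid
  expect_error(build_phantom(cohort_spec(grid_shape = c(10, 10, 8),
                                         seed = 1), "healthy"),
               "too small")
})

test_that("echo series simulator matches its stated signal model", {
  # hand-built single-compartment truth: pure 80 ms water, no myelin
  gs <- c(4, 4, 4)
  one <- array(1, gs); zero <- array(0, gs)
  truth <- structure(list(tissue_labels = array(3L, gs), mvf_true = zero,
                          avf_true = zero, nmvf_true = zero,
                          mwf_true = zero, v_ic_true = one,
                          v_iso_true = zero, voxel_size_mm = c(1, 1, 1),
                          lesion_factors = numeric(0), grid_shape = gs),
                     class = "phantom_truth")
  es <- simulate_echo_series(truth, n_echoes = 12, echo_spacing = 8,
                             refocusing_flip = 180, noise_sigma = 0,
                             seed = 1)
  sig <- es$data[1, 1, 1, ]
  expect_equal(sig, sig[1] / exp(-8 / 80) * exp(-(1:12) * 8 / 80),
               tolerance = 1e-12)

  # myelin water share of the amplitudes equals mwf_true by construction
  mwf <- array(0.2, gs)
  truth2 <- truth
  truth2$mwf_true <- mwf
  es2 <- simulate_echo_series(truth2, n_echoes = 12, noise_sigma = 0)
  # at t -> 0 the signal is the amplitude sum; decompose via the known
  # curves by solving the 3-compartment linear system at one voxel
  pars <- epg_params(165, 1000, 8, 12)
  X <- cbind(epg_decay_curve(20, pars), epg_decay_curve(80, pars),
             epg_decay_curve(2000, pars))
  a <- solve(crossprod(X), crossprod(X, es2$data[1, 1, 1, ]))
  expect_equal(a[1] / sum(a), 0.2, tolerance = 1e-9)

  # default-style run: strictly positive, decreasing mean signal
  ph <- cached_patient_phantom()
  es3 <- cached_noiseless_series()
  ms <- apply(es3$data, 4, function(v) mean(v[ph$vois$WM]))
  expect_true(all(ms > 0))
  # stimulated-echo pathways give an even/odd echo modulation at
  # imperfect refocusing; the pairwise-averaged train decays strictly
  pm <- (ms[seq(1, 47, 2)] + ms[seq(2, 48, 2)]) / 2
  expect_true(all(diff(pm) < 0))
  expect_lt(ms[48], 0.1 * ms[1])

  # parameter validation
  expect_error(simulate_echo_series(truth, refocusing_flip = 190),
               "flip")
  expect_error(simulate_echo_series(truth, echo_spacing = -1), "spacing")

  # seeded determinism and SNR contract
  sp <- small_spec(noise_sigma = 0.01)
  tr <- cached_patient_phantom()$truth
  n1 <- simulate_echo_series(tr, 12, 8, 165, 0.01, seed = 9)
  n2 <- simulate_echo_series(tr, 12, 8, 165, 0.01, seed = 9)
  expect_identical(n1$data, n2$data)
  wm <- tr$tissue_labels == 3L
  noiseless <- simulate_echo_series(tr, 12, 8, 165, 0, seed = 9)
  resid <- n1$data[, , , 1][wm] - noiseless$data[, , , 1][wm]
  snr <- mean(noiseless$data[, , , 1][wm]) / sd(resid)
  expect_lt(abs(snr - 1 / 0.01) / (1 / 0.01), 0.10)
})

test_that("MT quadruple simulator and its linearity by construction", {
  ph <- cached_patient_phantom()
  tr <- ph$truth
  q <- simulate_mt_quadruple(tr, forward_slope = 0.2, noise_sigma = 0,
                             seed = 1)
  ih <- compute_ihmtr(q)
  brain <- tr$tissue_labels > 0
  # noiseless ihMTR = forward_slope * mvf_true, exactly
  expect_lt(max(abs(vol_values(ih) - 0.2 * tr$mvf_true)[brain]), 1e-10)
  # mvf = 0 voxels (CSF) give exactly zero
  csf <- tr$tissue_labels == 1L
  expect_true(all(vol_values(ih)[csf] == 0))

  # direct arithmetic: slope 0.2 at mvf 0.3 gives 0.06 through the same
  # constructed quadruple
  i <- which.min(abs(tr$mvf_true - 0.3))
  expect_equal(vol_values(ih)[i], 0.2 * tr$mvf_true[i], tolerance = 1e-12)

  # noisy run is unbiased at the stated noise level
  qs <- lapply(1:8, function(s)
    compute_ihmtr(simulate_mt_quadruple(tr, 0.2, 0.005, seed = s)))
  wm <- tr$tissue_labels == 3L
  err <- mean(sapply(qs, function(m)
    mean(vol_values(m)[wm]) - mean(0.2 * tr$mvf_true[wm])))
  expect_lt(abs(err), 0.005)

  expect_error(simulate_mt_quadruple(tr, forward_slope = 2), "exceed")
  expect_error(simulate_mt_quadruple(tr, forward_slope = -1), "> 0")
})

test_that("gradient-echo triple follows the stated small-angle model", {
  tr <- cached_patient_phantom()$truth
  mi <- simulate_mtsat_inputs(tr, noise_sigma = 0, seed = 1)
  truthm <- attr(mi, "truth")
  brain <- tr$tissue_labels > 0

  # delta_true = 0 voxel: the MTw volume is a PDw-type acquisition with
  # its own flip/TR (same signal equation, delta = 0)
  csf <- which(tr$tissue_labels == 1L)
  a <- mi$flip_angles * pi / 180
  trs <- mi$repetition_times / 1000
  r1 <- truthm$r1_true[csf]; A <- truthm$a_true[csf]
  expect_equal(vol_values(mi$s_mtw)[csf],
               A * a[3] * trs[3] * r1 / (a[3]^2 / 2 + trs[3] * r1),
               tolerance = 1e-12)

  # forward + fit round trip recovers R1 (noiseless: exact, << 5%)
  ft <- fit_mtsat(mi)
  rel <- abs(vol_values(ft$r1) - truthm$r1_true)[brain] /
    truthm$r1_true[brain]
  expect_lt(max(rel, na.rm = TRUE), 0.05)

  # WM voxels have a higher T1w/PDw signal ratio than CSF
  wm <- tr$tissue_labels == 3L
  ratio <- vol_values(mi$s_t1w) / vol_values(mi$s_pdw)
  expect_gt(mean(ratio[wm]), mean(ratio[tr$tissue_labels == 1L]))

  expect_error(simulate_mtsat_inputs(tr, flip_angles = c(95, 6, 6)),
               "small-angle")
})

test_that("NODDI fraction emulator clips and preserves contrast", {
  tr <- cached_patient_phantom()$truth
  nf0 <- simulate_noddi_fractions(tr, noise_sigma = 0, seed = 1)
  expect_equal(vol_values(nf0$v_ic), tr$v_ic_true)
  expect_equal(vol_values(nf0$v_iso), tr$v_iso_true)

  nf <- simulate_noddi_fractions(tr, noise_sigma = 0.3, seed = 2)
  expect_true(all(vol_values(nf$v_ic) >= 0 & vol_values(nf$v_ic) <= 1))
  expect_true(all(vol_values(nf$v_iso) >= 0 & vol_values(nf$v_iso) <= 1))

  les <- tr$tissue_labels == 4L
  wm <- tr$tissue_labels == 3L
  expect_lt(mean(vol_values(nf0$v_ic)[les]), mean(vol_values(nf0$v_ic)[wm]))
})
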