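# T2 relaxometry: EPG decay curves against the isochromat oracle, the
# Lawson-Hanson and regularized NNLS contracts, flip-angle estimation, and
# both MWF mapping algorithms on the phantom.

test_that("EPG reduces to mono-exponential decay at 180 degrees", {
  pars <- epg_params(180, 1000, 8, 48)
  expect_equal(epg_decay_curve(80, pars), exp(-(1:48) * 8 / 80),
               tolerance = 1e-12)
  expect_equal(epg_decay_curve(80, pars)[6], exp(-48 / 80),
               tolerance = 1e-12)
  expect_error(epg_decay_curve(-5, pars), "t2")
})

test_that("EPG matches the isochromat-summation oracle at imperfect flips", {
  for (flip in c(150, 120, 97.5)) {
    pars <- epg_params(flip, 900, 10, 16)
    expect_lt(max(abs(epg_decay_curve(80, pars) -
                        oracle_iso_cpmg(80, 900, 10, flip, 16))), 1e-6)
  }
  # short T2 and long T2 corners
  pars <- epg_params(130, 1000, 8, 12)
  for (t2 in c(15, 2000))
    expect_lt(max(abs(epg_decay_curve(t2, pars) -
                        oracle_iso_cpmg(t2, 1000, 8, 130, 12))), 1e-6)
  # nonnegativity across the flip range
  for (flip in seq(20, 180, by = 20))
    expect_true(all(epg_decay_curve(60, epg_params(flip, 1000, 8, 32)) >=
                      -1e-12))
})

test_that("decay basis columns and conditioning behave as stated", {
  grid <- t2_grid(n_t2 = 12)
  pars <- epg_params(180, 1000, 8, 24)
  A <- build_decay_basis(grid, pars)
  expect_equal(A, outer((1:24) * 8, grid$t2_values,
                        function(te, t2) exp(-te / t2)),
               tolerance = 1e-12)
  expect_true(all(A[1, ] > 0))
  # ill-conditioning grows with grid density
  k1 <- kappa(build_decay_basis(t2_grid(n_t2 = 10), pars))
  k2 <- kappa(build_decay_basis(t2_grid(n_t2 = 40), pars))
  expect_gt(k2, k1)
})

test_that("NNLS solver agrees with an independent projected-gradient oracle", {
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(abs(rnorm(30 * 8)), 30, 8)
    x0 <- ifelse(runif(8) < 0.5, 0, runif(8))
    b <- A %*% x0 + rnorm(30, 0, 0.05)
    fit <- nnls_fit_voxel(drop(b), A, reg_factor = 1)
    xo <- oracle_nnls(A, drop(b))
    expect_equal(fit$amplitudes, xo, tolerance = 1e-5)
    # KKT: gradient nonnegative where x = 0, ~zero where x > 0
    g <- drop(crossprod(A, A %*% fit$amplitudes - b))
    expect_true(all(g[fit$amplitudes == 0] > -1e-8))
    expect_true(all(abs(g[fit$amplitudes > 0]) < 1e-8))
  }
})

test_that("regularized NNLS honors the misfit-inflation contract", {
  grid <- t2_grid()
  pars <- epg_params(160, 1000, 8, 32)
  A <- build_decay_basis(grid, pars)
  set.seed(3)
  b <- 0.8 * epg_decay_curve(78, pars) + 0.2 * epg_decay_curve(22, pars) +
    rnorm(32, 0, 0.005)
  f0 <- nnls_fit_voxel(b, A, reg_factor = 1)
  f <- nnls_fit_voxel(b, A, reg_factor = 1.02)
  expect_gt(f$mu, 0)
  expect_lt(abs(f$chi2 - 1.02 * f0$chi2), 1e-3 * 1.02 * f0$chi2)
  # regularized spectra are smoother (more active components)
  expect_gte(sum(f$amplitudes > 0), sum(f0$amplitudes > 0))
})

test_that("single- and two-compartment construct-and-fit recovery", {
  grid <- t2_grid()
  pars <- epg_params(165, 1000, 8, 48)
  A <- build_decay_basis(grid, pars)
  # pure grid atom: mass concentrates within one grid step
  j <- 20
  f <- nnls_fit_voxel(A[, j], A, reg_factor = 1, grid = grid)
  mass_near <- sum(f$amplitudes[max(1, j - 1):min(ncol(A), j + 1)])
  expect_gt(mass_near / sum(f$amplitudes), 1 - 1e-6)
  resid <- A %*% f$amplitudes - A[, j]
  expect_lt(sqrt(sum(resid^2)) / sqrt(sum(A[, j]^2)), 1e-6)

  # 20% myelin water at 20 ms + 80% at 80 ms
  b <- 0.2 * epg_decay_curve(20, pars) + 0.8 * epg_decay_curve(80, pars)
  f2 <- nnls_fit_voxel(b, A, reg_factor = 1, grid = grid)
  expect_lt(abs(f2$mwf - 0.20), 0.02)

  # zero signal is flagged, not an error
  fz <- nnls_fit_voxel(rep(0, 48), A)
  expect_true(fz$invalid)
  expect_true(is.na(fz$mwf))
})

test_that("flip-angle estimation recovers simulated refocusing angles", {
  grid <- t2_grid()
  pars <- epg_params(150, 1000, 8, 48)
  b <- 0.15 * epg_decay_curve(20, pars) + 0.85 * epg_decay_curve(80, pars)
  est <- estimate_flip_angle(b, grid, pars)
  expect_lt(abs(est$flip - 150), 2)
  expect_false(est$flat)

  pars180 <- epg_params(180, 1000, 8, 48)
  b180 <- 0.85 * epg_decay_curve(80, pars180) +
    0.15 * epg_decay_curve(20, pars180)
  est180 <- estimate_flip_angle(b180, grid, pars180)
  expect_gte(est180$flip, 178)

  expect_warning(ez <- estimate_flip_angle(rep(0, 48), grid, pars),
                 "flat")
  expect_true(ez$flat)
  expect_error(estimate_flip_angle(b, grid, pars, angle_grid = c(150, 160)),
               ">= 3")
})

test_that("voxelwise NNLS MWF map recovers the noiseless phantom", {
  ph <- cached_patient_phantom()
  tr <- ph$truth
  es <- cached_noiseless_series()
  es$mask <- ph$vois$WM
  grid <- t2_grid()
  pars <- epg_params(165, 1000, 8, 48)
  m <- fit_mwf_nnls(es, grid, pars)
  wm <- ph$vois$WM
  vals <- vol_values(m)
  expect_true(all(vals[wm] >= 0 & vals[wm] <= 1, na.rm = TRUE))
  expect_lt(mean(abs(vals - tr$mwf_true)[wm], na.rm = TRUE), 0.02)
  # flip-angle estimates track the simulated 165 degrees
  expect_lt(abs(mean(attr(m, "fit")$flip, na.rm = TRUE) - 165), 2)

  # an all-CSF voxel has essentially no myelin water signal
  escsf <- es
  escsf$mask <- array(FALSE, dim(vol_values(m)))
  csf_idx <- which(tr$tissue_labels == 1L)[1:5]
  escsf$mask[csf_idx] <- TRUE
  mcsf <- fit_mwf_nnls(escsf, grid, pars)
  expect_lt(max(vol_values(mcsf)[csf_idx], na.rm = TRUE), 0.01)
})

test_that("SPIJN recovers a two-component world and matches NNLS in WM", {
  # on-grid two-pool world: dictionary contains 20 and 80 ms exactly
  grid2 <- t2_grid(10, 2560, n_t2 = 9, window_max = 41)
  expect_true(all(c(20, 80) %in% round(grid2$t2_values, 6)))
  pars <- epg_params(165, 1000, 8, 32)
  A <- build_decay_basis(grid2, pars)
  set.seed(8)
  nv <- 60
  mwfs <- runif(nv, 0.05, 0.3)
  sig <- A[, which.min(abs(grid2$t2_values - 20))] %*% t(mwfs) +
    A[, which.min(abs(grid2$t2_values - 80))] %*% t(1 - mwfs) # 32 x nv
  es <- echo_series(aperm(array(sig, c(32, nv, 1, 1)), c(2, 3, 4, 1)),
                    echo_times = (1:32) * 8)
  m <- fit_mwf_spijn(es, grid2, pars, sparsity_weight = 0.02,
                     max_components = 4)
  supp <- attr(m, "fit")$support_t2
  expect_equal(sort(supp), c(20, 80), tolerance = 1e-9)
  expect_equal(as.vector(vol_values(m)), mwfs, tolerance = 1e-8)

  # lambda = 0 equals unregularized voxelwise NNLS
  grid <- t2_grid()
  ph <- cached_patient_phantom()
  es2 <- cached_noiseless_series()
  idx <- which(ph$vois$WM)[1:40]
  es2$mask <- array(FALSE, dim(ph$truth$mvf_true))
  es2$mask[idx] <- TRUE
  pars48 <- epg_params(165, 1000, 8, 48)
  m0 <- fit_mwf_spijn(es2, grid, pars48, sparsity_weight = 0,
                      max_components = 40)
  A48 <- build_decay_basis(grid, pars48)
  win <- grid$t2_values <= grid$myelin_window[2]
  gs <- dim(ph$truth$mvf_true)
  for (i in idx[c(1, 17, 33)]) {
    co <- arrayInd(i, gs)
    b <- cached_noiseless_series()$data[co[1], co[2], co[3], ]
    x <- drop(gratiomap:::cpp_nnls(A48, b)$x)
    expect_equal(vol_values(m0)[i], sum(x[win]) / sum(x),
                 tolerance = 1e-8)
  }

  # cross-method agreement in healthy WM (noiseless)
  es3 <- cached_noiseless_series()
  es3$mask <- ph$vois$WM
  mn <- fit_mwf_nnls(es3, grid, pars48)
  msp <- fit_mwf_spijn(es3, grid, pars48)
  f <- attr(msp, "fit")
  expect_true(f$converged)
  expect_lte(length(f$support_t2), 6)
  wm <- ph$vois$WM
  expect_lt(abs(mean(vol_values(mn)[wm], na.rm = TRUE) -
                  mean(vol_values(msp)[wm], na.rm = TRUE)), 0.02)
  expect_lt(mean(abs(vol_values(msp) - ph$truth$mwf_true)[wm],
                 na.rm = TRUE), 0.02)
})
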