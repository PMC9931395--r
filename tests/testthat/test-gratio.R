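# Myelin/axonal volume fractions and aggregate g-ratio: the hydration
# model transform and its inverse, linear scalings, the axonal model with
# and without non-myelin macromolecules, splenium calibration, and the
# five-channel pipeline identity on the self-consistent phantom.

test_that("hydration-model transform: printed values, monotonicity, inverse", {
  m <- hydration_model()
  expect_equal(m$kappa_my, 0.36)
  expect_equal(m$kappa_nm, 0.86)
  expect_equal(mvf_from_mwf(0), 0)
  expect_equal(mvf_from_mwf(1), 1)
  # cohort-mean lesion MWF values print as MVF 0.17 / 0.09
  expect_equal(round(mvf_from_mwf(0.080), 2), 0.17)
  expect_equal(mvf_from_mwf(0.080), 0.172, tolerance = 1e-3)
  expect_equal(round(mvf_from_mwf(0.041), 2), 0.09)
  expect_equal(mvf_from_mwf(0.041), 0.0927, tolerance = 1e-3)

  x <- seq(0, 1, by = 0.01)
  y <- mvf_from_mwf(x)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y <= 1))
  # analytic inverse round-trips to machine precision
  expect_lt(max(abs(mwf_from_mvf(y) - x)), 1e-12)
  expect_equal(mwf_from_mvf(0.172), 0.080, tolerance = 1e-3)
  expect_equal(mwf_from_mvf(0), 0)
  expect_equal(mwf_from_mvf(1), 1)
  expect_error(hydration_model(0.9, 0.8), "kappa")
})

test_that("linear and MTV-based MVF models", {
  expect_equal(mvf_linear(0.3, 0.2), 0.06, ignore_attr = TRUE)
  expect_equal(mvf_linear(0, 5), 0, ignore_attr = TRUE)
  v <- mvf_linear(c(0.1, 0.9), 2)
  expect_equal(as.vector(v), c(0.2, 1)) # clipped
  expect_equal(attr(v, "qc")$n_clipped, 1)
  expect_error(mvf_linear(0.3, -1), "positive")

  mtv <- volume_map(array(0.31, c(2, 2, 2)), role = "MTV")
  mvf <- mvf_from_mtv(mtv)
  expect_equal(vol_values(mvf), vol_values(mtv))
  expect_equal(mvf$role, "MVF")
  # purity: mutating the output never touches the input
  mvf$values[1] <- 0.99
  expect_equal(vol_values(mtv)[1], 0.31)
})

test_that("axonal volume fraction model and the NMVF extension", {
  nf <- list(v_ic = 0.6, v_iso = 0.1)
  expect_equal(compute_avf(0.3, nf), 0.378, ignore_attr = TRUE)
  expect_equal(compute_avf(0.3, nf, nmvf = 0.1), 0.324,
               ignore_attr = TRUE)
  expect_equal(compute_avf(0, list(v_ic = 1, v_iso = 0)), 1,
               ignore_attr = TRUE)
  # nmvf = 0 reduces the extended model to the primary one exactly
  set.seed(1)
  mvf <- runif(50, 0, 0.5)
  vic <- runif(50); viso <- runif(50)
  expect_equal(compute_avf(mvf, list(v_ic = vic, v_iso = viso), 0),
               (1 - mvf) * (1 - viso) * vic, ignore_attr = TRUE)
  # conservation: MVF + AVF + NMVF <= 1
  nm <- pmin(runif(50, 0, 0.3), 1 - mvf)
  avf <- compute_avf(mvf, list(v_ic = vic, v_iso = viso), nm)
  expect_true(all(mvf + avf + nm <= 1 + 1e-12))
  # over-unity macromolecular content invalidates the voxel
  bad <- compute_avf(c(0.7, 0.2), list(v_ic = c(1, 1), v_iso = c(0, 0)),
                     c(0.5, 0))
  expect_true(is.nan(bad[1]) && !is.nan(bad[2]))
  expect_equal(attr(bad, "qc")$n_invalid, 1)
})

test_that("aggregate g-ratio formula and monotonicity", {
  expect_equal(compute_gratio(0, 0.5), 1, ignore_attr = TRUE)
  expect_equal(compute_gratio(0.25, 0.25), sqrt(0.5), ignore_attr = TRUE)
  expect_equal(compute_gratio(0.3, 0.4), sqrt(0.4 / 0.7),
               ignore_attr = TRUE)
  z <- compute_gratio(c(0, 0.1), c(0, 0.1))
  expect_true(is.nan(z[1]))
  expect_equal(attr(z, "qc")$n_invalid, 1)
  expect_error(compute_gratio(-0.1, 0.5), "nonnegative")

  # strictly decreasing in MVF at fixed NODDI fractions (AVF via the
  # axonal model) -- the basis of calibration well-posedness
  mvf <- seq(0, 0.9, by = 0.01)
  avf <- compute_avf(mvf, list(v_ic = rep(0.7, length(mvf)),
                               v_iso = rep(0.05, length(mvf))))
  g <- compute_gratio(mvf, avf)
  expect_true(all(diff(g) < 0))

  # increasing NMVF at fixed measured MVF decreases AVF and g
  a0 <- compute_avf(0.3, list(v_ic = 0.7, v_iso = 0.05), 0)
  a1 <- compute_avf(0.3, list(v_ic = 0.7, v_iso = 0.05), 0.15)
  expect_lt(a1, a0)
  expect_lt(compute_gratio(0.3, a1), compute_gratio(0.3, a0))
})

test_that("splenium calibration: closed form, recovery, monotonicity", {
  # single voxel, x = 1, v_ic = 1, v_iso = 0: g^2 = 1 - alpha
  one <- array(1, c(1, 1, 1))
  x <- volume_map(one)
  nf <- list(v_ic = volume_map(one), v_iso = volume_map(one * 0))
  msk <- array(TRUE, c(1, 1, 1))
  a <- calibrate_alpha(list(x), list(nf), list(msk), g_target = 0.7)
  expect_equal(a, 1 - 0.49, tolerance = 1e-7)

  # self-consistency: maps generated as x = mvf_true / alpha0 recover
  # alpha0 when targeting the true cohort splenium g
  spec <- small_spec(seed = 3)
  subs <- lapply(1:3, function(i)
    simulate_subject(spec, "healthy", 100 + i,
                     channels = c("mt", "noddi")))
  ihs <- lapply(subs, function(s) compute_ihmtr(s$mt_quad))
  spl <- lapply(subs, function(s) s$vois$splenium)
  nfs <- lapply(subs, `[[`, "noddi")
  g_true <- mean(sapply(subs, function(s) {
    m <- s$vois$splenium
    mvf <- s$truth$mvf_true[m]
    avf <- s$truth$avf_true[m]
    mean(sqrt(avf / (avf + mvf)))
  }))
  a0 <- calibrate_alpha(ihs, nfs, spl, g_target = g_true)
  expect_equal(a0, 1 / spec$forward_slope, tolerance = 1e-5)

  # larger targets need smaller scalings
  a_small <- calibrate_alpha(ihs, nfs, spl, g_target = 0.9)
  a_big <- calibrate_alpha(ihs, nfs, spl, g_target = 0.6)
  expect_lt(a_small, a0)
  expect_gt(a_big, a0)

  expect_error(calibrate_alpha(ihs, nfs, spl, g_target = 0.01),
               "attainable")
  expect_error(calibrate_alpha(ihs, nfs, list(spl[[1]] & FALSE, spl[[2]],
                                              spl[[3]]), g_target = 0.7),
               "empty")
})

test_that("five-channel pipeline identity on the self-consistent phantom", {
  # noiseless world with nmvf = 0: every channel encodes mvf_true, so all
  # five g maps must agree (up to the calibration bisection tolerance)
  spec <- small_spec(seed = 21)
  subs <- lapply(1:3, function(i)
    simulate_subject(spec, "healthy", 300 + i,
                     channels = c("mt", "mtsat", "noddi")))
  model <- hydration_model()
  maps_per <- lapply(subs, function(s) {
    ft <- fit_mtsat(s$mtsat_in)
    pd <- calibrate_pd(ft$a_app, pd_calibration("csf100"), s$vois)
    list(mwf_nnls = volume_map(s$truth$mwf_true), # exact MWF channel
         mwf_spijn = volume_map(s$truth$mwf_true),
         ihmtr = compute_ihmtr(s$mt_quad),
         mtsat = ft$mtsat,
         mtv = compute_mtv(pd))
  })
  g_true <- mean(sapply(subs, function(s) {
    m <- s$vois$splenium
    mvf <- s$truth$mvf_true[m]; avf <- s$truth$avf_true[m]
    mean(sqrt(avf / (avf + mvf)))
  }))
  spl <- lapply(subs, function(s) s$vois$splenium)
  nfs <- lapply(subs, `[[`, "noddi")
  alphas <- list(
    ihmtr = calibrate_alpha(lapply(maps_per, `[[`, "ihmtr"), nfs, spl,
                            g_target = g_true),
    mtsat = calibrate_alpha(lapply(maps_per, `[[`, "mtsat"), nfs, spl,
                            g_target = g_true))
  s1 <- subs[[1]]
  brain <- s1$truth$tissue_labels > 0L
  gmaps <- lapply(c("mwf_nnls", "mwf_spijn", "ihmtr", "mtsat", "mtv"),
                  function(me) {
    res <- run_gratio_pipeline(maps_per[[1]], s1$noddi, method = me,
                               alpha = alphas[[me]], model = model)
    vol_values(res$g)
  })
  for (k in 2:5)
    expect_lt(max(abs(gmaps[[k]] - gmaps[[1]])[brain], na.rm = TRUE),
              1e-6)

  # mtv path equals the closed-form composition voxelwise
  res <- run_gratio_pipeline(maps_per[[1]], s1$noddi, method = "mtv",
                             model = model)
  mtv <- vol_values(maps_per[[1]]$mtv)
  vic <- vol_values(s1$noddi$v_ic); viso <- vol_values(s1$noddi$v_iso)
  avf <- (1 - mtv) * (1 - viso) * vic
  gref <- sqrt(avf / (avf + mtv))
  d <- abs(vol_values(res$g) - gref)
  expect_lt(max(d[brain & is.finite(gref) &
                    is.finite(vol_values(res$g))], na.rm = TRUE), 1e-12)

  # missing calibration is a configuration error
  expect_error(run_gratio_pipeline(maps_per[[1]], s1$noddi,
                                   method = "ihmtr"), "alpha")
})
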