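tmg <- dce_timing()
aif <- aif_model()
cp_curve <- population_aif(tmg, aif)

test_that("population AIF is zero pre-bolus, peaks at dose scale, then decays", {
  t_s <- cp_curve$times_s
  onset <- tmg$injection_time_s + aif$onset_delay_s
  expect_true(all(cp_curve$values[t_s < onset] == 0))
  post <- cp_curve$values[t_s >= onset]
  expect_true(all(diff(post) < 0))
  # with the arrival aligned to the frame grid, the peak sample is exactly
  # the dose scale (a1 + a2 = 1)
  tm2 <- dce_timing(n_frames = 120, total_duration_s = 240,
                    injection_time_s = 60)
  aif0 <- aif_model(onset_delay_s = 0)
  cp2 <- population_aif(tm2, aif0)
  expect_equal(cp2$values[cp2$times_s == 60], aif0$dose_scale_mM)
  expect_error(aif_model(a1 = 0.7, a2 = 0.2), "a1")
  expect_error(aif_model(m1_per_min = 0.05, m2_per_min = 0.06), "m1")
})

test_that("signal conversion is exact against its own forward model", {
  tr <- tiny_truth(ktrans = 0.3, ve = 0.35, vp = 0.04, t1 = 1800)
  d <- simulate_dce_series(tr, tmg, aif, dce_conversion(), noise_sd = 0)
  ct_true <- tofts_concentration(cp_curve$times_s, cp_curve$values,
                                 0.3, 0.35, 0.04)
  sig <- d$frames[1, 1, ]
  conc <- signal_to_concentration(sig, tmg, t1_0_ms = 1800)
  expect_lt(max(abs(conc$values[, 1] - ct_true)), 1e-9)

  # flat signal gives zero concentration and zero enhancement
  flat <- rep(sig[1], tmg$n_frames)
  c0 <- signal_to_concentration(flat, tmg, t1_0_ms = 1800)
  expect_lt(max(abs(c0$values)), 1e-12)
  e0 <- signal_to_concentration(flat, tmg, conversion = dce_conversion("relative"))
  expect_lt(max(abs(e0$values)), 1e-12)

  # relative enhancement is invariant to global scaling
  e1 <- signal_to_concentration(sig, tmg, conversion = dce_conversion("relative"))
  e2 <- signal_to_concentration(2 * sig, tmg,
                                conversion = dce_conversion("relative"))
  expect_equal(e1$values, e2$values, tolerance = 1e-12)
})

test_that("extended Tofts with vp = 0 matches an independent standard Tofts code", {
  set.seed(77)
  for (i in 1:50) {
    kt <- runif(1, 0.01, 2); ve <- runif(1, 0.05, 0.8)
    a <- tofts_concentration(cp_curve$times_s, cp_curve$values, kt, ve, 0)
    b <- standard_tofts_scalar(cp_curve$times_s, cp_curve$values, kt, ve)
    expect_lt(max(abs(a - b)), 1e-10)
  }
})

test_that("discrete convolution converges to the analytic biexponential solution", {
  kt <- 0.25; ve <- 0.4; vp <- 0.02
  err_at <- function(n) {
    tm <- dce_timing(n_frames = n, total_duration_s = 1200,
                     injection_time_s = 60)
    cp <- population_aif(tm, aif)
    num <- tofts_concentration(cp$times_s, cp$values, kt, ve, vp)
    ana <- analytic_tofts_biexp(cp$times_s, aif, tm, kt, ve, vp)
    max(abs(num - ana)) / max(ana)
  }
  # the bolus arrival is a step in Cp, so the piecewise-linear scheme is
  # first-order accurate near the kink: refining the grid 10x must shrink
  # the error ~10x
  e1 <- err_at(610)
  e2 <- err_at(6100)
  expect_lt(e1, 0.08)
  expect_lt(e2, e1 / 8)
})

test_that("extended Tofts fit recovers known parameters and degenerate cases", {
  ct <- tofts_concentration(cp_curve$times_s, cp_curve$values, 0.25, 0.4, 0.02)
  fit <- fit_extended_tofts(ct, cp_curve$values, times_s = cp_curve$times_s)
  expect_lt(abs(fit$ktrans_per_min - 0.25) / 0.25, 0.01)
  expect_lt(abs(fit$ve_frac - 0.4) / 0.4, 0.01)
  expect_lt(abs(fit$vp_frac - 0.02) / 0.02, 0.01)
  expect_false(fit$degenerate)

  # oracle: dense grid search over (Ktrans, ve) at the true vp
  oracle <- grid_search_tofts(ct, cp_curve$values, cp_curve$times_s, 0.02,
                              c(0.15, 0.35), c(0.3, 0.5), n = 41)
  expect_lt(abs(fit$ktrans_per_min - oracle$ktrans), 0.006)
  expect_lt(abs(fit$ve_frac - oracle$ve), 0.006)

  plasma <- fit_extended_tofts(0.05 * cp_curve$values, cp_curve$values,
                               times_s = cp_curve$times_s)
  expect_equal(plasma$vp_frac, 0.05, tolerance = 1e-6)
  expect_lt(plasma$ktrans_per_min, 1e-6)

  zero <- fit_extended_tofts(rep(0, tmg$n_frames), cp_curve$values,
                             times_s = cp_curve$times_s)
  expect_true(zero$degenerate)
  expect_equal(zero$ktrans_per_min, 0)
  expect_equal(zero$vp_frac, 0)
})

test_that("noisy Tofts recovery keeps the median Ktrans error under 10%", {
  set.seed(5)
  errs <- vapply(1:25, function(i) {
    kt <- runif(1, 0.05, 1); ve <- runif(1, 0.1, 0.6); vp <- runif(1, 0, 0.1)
    ct <- tofts_concentration(cp_curve$times_s, cp_curve$values, kt, ve, vp)
    noisy <- ct + rnorm(length(ct), 0, 0.02 * max(ct))
    fit <- fit_extended_tofts(noisy, cp_curve$values,
                              times_s = cp_curve$times_s)
    abs(fit$ktrans_per_min - kt) / kt
  }, 0)
  expect_lt(stats::median(errs), 0.10)
})

test_that("semi-quantitative metrics match closed forms", {
  t_s <- frame_times(tmg)
  k <- 0.002  # enhancement per second
  ramp <- pmax(t_s - tmg$injection_time_s, 0) * k
  sq <- semiquant_metrics(concentration_curve(t_s, ramp, "enhancement"), tmg)
  t_end_min <- (max(t_s) - tmg$injection_time_s) / 60
  expect_equal(sq$slope_max, k * 60, tolerance = 1e-9)
  expect_equal(sq$peak_enhancement, k * (max(t_s) - tmg$injection_time_s),
               tolerance = 1e-12)
  expect_equal(sq$auc, (k * 60) * t_end_min^2 / 2, tolerance = 1e-4)

  zero <- semiquant_metrics(concentration_curve(t_s, rep(0, length(t_s))), tmg)
  expect_equal(zero$peak_enhancement, 0)
  expect_equal(zero$slope_max, 0)
  expect_equal(zero$auc, 0)

  # trapezoidal AUC of a sinusoid on a 1200-point grid vs analytic integral
  tm2 <- dce_timing(n_frames = 1200, total_duration_s = 1200,
                    injection_time_s = 60)
  tt <- frame_times(tm2)
  w <- 2 * pi / 600
  sine <- sin(w * tt)
  sq2 <- semiquant_metrics(concentration_curve(tt, sine, "enhancement"), tm2,
                           smooth_window = 1)
  analytic <- (cos(w * 60) - cos(w * max(tt))) / w / 60   # minutes
  expect_equal(sq2$auc, analytic, tolerance = 1e-4)

  expect_error(semiquant_metrics(concentration_curve(t_s, ramp), tmg,
                                 smooth_window = 2000), "window")
})

test_that("ROI curves are masked means with the expected linearity", {
  tr <- make_phantom("hom", 6, c(32, 32), seed = 8)
  tm <- dce_timing(n_frames = 40, total_duration_s = 80, injection_time_s = 20)
  d <- simulate_dce_series(tr, tm, noise_sd = 1, seed = 2)

  idx <- which(tr$tumor_mask$grid)
  single <- matrix(FALSE, 32, 32); single[idx[1]] <- TRUE
  rc <- arrayInd(idx[1], c(32, 32))
  expect_equal(roi_curve(d, roi_mask(single), tm)$values,
               as.vector(d$frames[rc[1], rc[2], ]))

  uni <- d; uni$frames[, , 3] <- 7
  expect_equal(roi_curve(uni, tr$tumor_mask, tm)$values[3], 7)

  g1 <- matrix(FALSE, 32, 32); g1[idx[1:10]] <- TRUE
  g2 <- matrix(FALSE, 32, 32); g2[idx[11:40]] <- TRUE
  gu <- g1 | g2
  c1 <- roi_curve(d, roi_mask(g1), tm)$values
  c2 <- roi_curve(d, roi_mask(g2), tm)$values
  cu <- roi_curve(d, roi_mask(gu), tm)$values
  expect_equal((10 * c1 + 30 * c2) / 40, cu, tolerance = 1e-12)
})

test_that("voxel-wise Tofts maps recover truth and separate the phenotypes", {
  tr_het <- make_phantom("het", 9, c(32, 32), seed = 6)
  tr_hom <- make_phantom("hom", 9, c(32, 32), seed = 6)
  tm <- dce_timing(n_frames = 200, total_duration_s = 1200,
                   injection_time_s = 60)
  cp <- population_aif(tm, aif)
  fit_map_of <- function(tr) {
    d <- simulate_dce_series(tr, tm, aif, noise_sd = 0)
    flat <- matrix(d$frames, 32 * 32, tm$n_frames)
    conc <- signal_to_concentration(t(flat), tm,
                                    t1_0_ms = as.vector(tr$t1_ms$values))
    fit_dce_map(conc, cp, tr$tumor_mask)
  }
  maps_het <- fit_map_of(tr_het)
  rel <- abs(maps_het$ktrans$values - tr_het$ktrans_per_min$values) /
    pmax(tr_het$ktrans_per_min$values, 1e-3)
  sel <- maps_het$ktrans$valid & tr_het$ktrans_per_min$values > 0.05
  expect_lt(stats::median(rel[sel]), 0.02)

  maps_hom <- fit_map_of(tr_hom)
  rim <- tr_het$tumor_mask$grid & !tr_het$necrosis_mask$grid
  expect_gt(mean(maps_het$ktrans$values[rim & maps_het$ktrans$valid]),
            mean(maps_hom$ktrans$values[tr_hom$tumor_mask$grid &
                                          maps_hom$ktrans$valid]))
})
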