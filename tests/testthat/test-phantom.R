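test_that("phantom geometry follows phenotype and day", {
  hom <- make_phantom("homogeneous_nonmetastatic", 3, c(32, 32), seed = 1)
  expect_lt(necrotic_fraction(hom), 0.05)

  het3 <- make_phantom("heterogeneous_metastatic", 3, c(64, 64), seed = 1)
  het6 <- make_phantom("heterogeneous_metastatic", 6, c(64, 64), seed = 1)
  het9 <- make_phantom("heterogeneous_metastatic", 9, c(64, 64), seed = 1)
  expect_gt(necrotic_fraction(het9), necrotic_fraction(het3))
  expect_gt(necrotic_fraction(het9), necrotic_fraction(het6))
  expect_gt(necrotic_fraction(het6), necrotic_fraction(het3))
  # necrosis strictly inside the tumor
  expect_true(all(het9$tumor_mask$grid[het9$necrosis_mask$grid]))
  # the faster-growing phenotype is larger at matched day
  expect_gt(n_voxels(het9$tumor_mask),
            n_voxels(make_phantom("hom", 9, c(64, 64), seed = 1)$tumor_mask))
})

test_that("phantom truth maps satisfy the physical invariants", {
  for (ph in c("heterogeneous_metastatic", "homogeneous_nonmetastatic")) {
    tr <- make_phantom(ph, 9, c(32, 32), seed = 3)
    expect_true(all(tr$t1_ms$values > 0))
    expect_true(all(tr$t2_ms$values > 0))
    expect_true(all(tr$adc_mm2_per_s$values >= 1e-4 &
                      tr$adc_mm2_per_s$values <= 4e-3))
    expect_true(all(tr$ktrans_per_min$values >= 0))
    expect_true(all(tr$ve_frac$values + tr$vp_frac$values <= 1 + 1e-12))
  }
})

test_that("phantom generation is deterministic and rejects bad input", {
  a <- make_phantom("het", 6, c(64, 64), seed = 7)
  b <- make_phantom("het", 6, c(64, 64), seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a$t1_ms$values, make_phantom("het", 6, c(64, 64), seed = 8)$t1_ms$values))
  expect_error(make_phantom("spindle", 3), "should be one of")
  expect_error(make_phantom("het", 4), "day")
  expect_error(make_phantom("het", 3, c(8, 8)), "16")
})

test_that("forward T1/T2/DWI signals match the closed-form decay laws", {
  tr <- tiny_truth(t1 = 1000, t2 = 40, adc = 1e-3, s0 = 500)
  s <- simulate_t1_series(tr, tr_list = c(1e-6, 123, 7500), noise_sd = 0)
  expect_equal(s$frames[1, 1, 3], 500 * (1 - exp(-7.5)), tolerance = 1e-12)
  expect_lt(s$frames[1, 1, 1], 1e-6)  # TR -> 0 limit

  tr2 <- tiny_truth(t2 = 40, s0 = 800)
  s2 <- simulate_t2_series(tr2, te_list = c(1e-6, 40, 90), noise_sd = 0)
  expect_equal(s2$frames[1, 1, 2], 800 / exp(1), tolerance = 1e-12)
  expect_equal(s2$frames[1, 1, 1], 800, tolerance = 1e-4)  # TE -> 0

  s3 <- simulate_dwi_series(tr, b_values = c(0, 1000), noise_sd = 0)
  expect_equal(s3$frames[1, 1, 1], 500)
  expect_equal(s3$frames[1, 1, 2], 500 / exp(1), tolerance = 1e-12)
})

test_that("default acquisition axes match the mapping protocol", {
  expect_setequal(default_tr_ms(), c(7500, 5000, 3000, 1500, 800, 400, 311, 123))
  expect_equal(default_te_ms(), c(10, 30, 50, 70, 90))
  b <- default_b_values()
  expect_length(b, 12)
  expect_equal(max(b), 2200)
  tmg <- dce_timing()
  expect_equal(tmg$n_frames, 610L)
  expect_equal(tmg$frame_interval_s, 1200 / 610)
  expect_equal(tmg$injection_time_s, 60)
})

test_that("simulated noise is calibrated and seeded", {
  tr <- tiny_truth()
  # >10,000 independent noise samples: empirical sd within 5% of requested
  clean <- simulate_dwi_series(tr, noise_sd = 0)$frames
  resid <- unlist(lapply(1:4, function(s)
    simulate_dwi_series(tr, noise_sd = 4, seed = s)$frames - clean))
  expect_lt(abs(stats::sd(resid) - 4) / 4, 0.05)
  expect_lt(abs(mean(resid)), 0.15)

  a <- simulate_dwi_series(tr, noise_sd = 3, seed = 9)
  b <- simulate_dwi_series(tr, noise_sd = 3, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames,
                         simulate_dwi_series(tr, noise_sd = 3, seed = 10)$frames))
  expect_error(simulate_t1_series(tr, noise_sd = -1), "noise_sd")
  expect_true(all(simulate_t2_series(tr, noise_sd = 50, seed = 1)$frames >= 0))
})

test_that("DCE simulation has no enhancement without exchange or before injection", {
  tr <- tiny_truth(ktrans = 0, vp = 0, ve = 0.4, gd = 0)
  tmg <- dce_timing(n_frames = 60, total_duration_s = 120,
                    injection_time_s = 30)
  d <- simulate_dce_series(tr, tmg, noise_sd = 0)
  v <- d$frames[1, 1, ]
  expect_equal(max(v) - min(v), 0, tolerance = 1e-12)

  tr2 <- tiny_truth()
  d2 <- simulate_dce_series(tr2, tmg, noise_sd = 0)
  pre <- frame_times(tmg) < 30
  v2 <- d2$frames[1, 1, ]
  expect_equal(max(v2[pre]) - min(v2[pre]), 0, tolerance = 1e-12)
  expect_gt(max(v2), v2[1])
  expect_error(dce_timing(60, 120, 130), "injection")
})

test_that("LA-ICP-MS simulator produces exact standards and geometric line scans", {
  tr <- make_phantom("het", 6, c(32, 32), seed = 2)
  ex <- simulate_laicpms_experiment(tr, standard_levels = c(0, 300, 600),
                                    sensitivity = 10, blank_sd = 0,
                                    intercept = 50, seed = 1)
  lvl600 <- ex$standards$intensity[ex$standards$concentration == 600]
  expect_equal(lvl600, rep(50 + 6000, 10))
  expect_true(any(ex$standards$concentration == 0))

  g <- tr$tumor_mask$grid
  h_um <- diff(range(which(rowSums(g) > 0))) + 1
  h_um <- h_um * tr$pixel_spacing[1] * 1000
  expect_equal(nrow(ex$linescan$intensity), ceiling(h_um / 15))
  expect_error(simulate_laicpms_experiment(tr, standard_levels = c(100, 600)),
               "blank")
})

test_that("cohort generation is deterministic with distinct per-tumor seeds", {
  co <- make_cohort(8, c(3, 6, 9), seed = 42, grid_shape = c(32, 32))
  expect_length(co$phantoms, 48)
  expect_equal(nrow(co$manifest), 48)
  expect_false(anyDuplicated(co$manifest$seed) > 0)
  co2 <- make_cohort(8, c(3, 6, 9), seed = 42, grid_shape = c(32, 32))
  expect_identical(co$manifest, co2$manifest)

  f <- tempfile(fileext = ".csv")
  write_manifest(co$manifest, f)
  expect_equal(read_manifest(f), co$manifest)
  expect_error(make_cohort(1), "n_per_group")
})
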