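test_that("noise-free phantom series are recovered to solver precision", {
  tr <- make_phantom("het", 9, c(32, 32), seed = 5)
  mask <- tr$tumor_mask

  t1 <- fit_t1_map(simulate_t1_series(tr, noise_sd = 0), mask)
  rel <- abs(t1$values - tr$t1_ms$values) / tr$t1_ms$values
  expect_true(all(t1$valid[mask$grid]))
  expect_lt(max(rel[t1$valid]), 1e-5)

  t2 <- fit_t2_map(simulate_t2_series(tr, noise_sd = 0), mask)
  rel2 <- abs(t2$values - tr$t2_ms$values) / tr$t2_ms$values
  expect_lt(max(rel2[t2$valid]), 1e-5)

  adc <- fit_adc_map(simulate_dwi_series(tr, noise_sd = 0), mask)
  rel3 <- abs(adc$values - tr$adc_mm2_per_s$values) / tr$adc_mm2_per_s$values
  expect_lt(max(rel3[adc$valid]), 1e-5)
})

test_that("bounded separable fits agree with exhaustive grid-search oracles", {
  set.seed(41)
  tr_ms <- default_tr_ms()
  for (i in 1:6) {
    t1_true <- runif(1, 500, 3000)
    s0 <- runif(1, 300, 700)
    y <- s0 * (1 - exp(-tr_ms / t1_true)) + rnorm(length(tr_ms), 0, 0.01 * s0)
    tr <- tiny_truth()
    s <- image_series(array(pmax(rep(y, each = 256), 0), c(16, 16, 8)),
                      "repetition_time", tr_ms)
    fit <- fit_t1_map(s, roi_mask(matrix(TRUE, 16, 16)))
    oracle <- grid_search_t1(tr_ms, y, c(t1_true - 300, t1_true + 300), 0.1)
    expect_equal(fit$values[1, 1], oracle$t1, tolerance = 0.2)
  }
  te_ms <- default_te_ms()
  for (i in 1:6) {
    t2_true <- runif(1, 20, 90)
    y <- 600 * exp(-te_ms / t2_true) + rnorm(5, 0, 3)
    s <- image_series(array(pmax(rep(y, each = 4), 0), c(2, 2, 5)),
                      "echo_time", te_ms)
    fit <- fit_t2_map(s, roi_mask(matrix(TRUE, 2, 2)))
    oracle <- grid_search_t2(te_ms, y, c(10, 150), 0.01)
    expect_equal(fit$values[1, 1], oracle, tolerance = 0.02)
  }
})

test_that("nonlinear optimizer cross-check: nlsLM finds the same T1", {
  skip_if_not_installed("minpack.lm")
  tr_ms <- default_tr_ms()
  set.seed(13)
  y <- 500 * (1 - exp(-tr_ms / 1800)) + rnorm(8, 0, 4)
  s <- image_series(array(pmax(rep(y, each = 4), 0), c(2, 2, 8)),
                    "repetition_time", tr_ms)
  fit <- fit_t1_map(s, roi_mask(matrix(TRUE, 2, 2)))
  nls_fit <- minpack.lm::nlsLM(y ~ A + C * (1 - exp(-tr_ms / T1)),
                               start = list(A = 0, C = 500, T1 = 1500))
  expect_equal(fit$values[1, 1], coef(nls_fit)[["T1"]], tolerance = 1e-4)
})

test_that("log-linear closed forms match the nonlinear fits on clean decays", {
  b <- default_b_values()
  y <- 700 * exp(-b * 1.3e-3)
  s <- image_series(array(rep(y, each = 4), c(2, 2, 12)), "b_value", b)
  fit <- fit_adc_map(s, roi_mask(matrix(TRUE, 2, 2)))
  expect_lt(abs(fit$values[1, 1] - loglinear_adc(b, y)), 1e-9)
  expect_lt(abs(fit$values[1, 1] - 1.3e-3), 1e-9)

  te <- default_te_ms()
  y2 <- 800 * exp(-te / 55)   # A = 0 exactly
  s2 <- image_series(array(rep(y2, each = 4), c(2, 2, 5)), "echo_time", te)
  fit2 <- fit_t2_map(s2, roi_mask(matrix(TRUE, 2, 2)))
  loglin_t2 <- -1 / stats::lm.fit(cbind(1, te), log(y2))$coefficients[2]
  expect_equal(fit2$values[1, 1], unname(loglin_t2), tolerance = 1e-8 * 55)
})

test_that("degenerate voxels are flagged invalid rather than fitted", {
  tr_ms <- default_tr_ms()
  const <- image_series(array(100, c(2, 2, 8)), "repetition_time", tr_ms)
  f <- fit_t1_map(const, roi_mask(matrix(TRUE, 2, 2)))
  expect_false(any(f$valid))

  zero <- image_series(array(0, c(2, 2, 5)), "echo_time", default_te_ms())
  f2 <- fit_t2_map(zero, roi_mask(matrix(TRUE, 2, 2)))
  expect_false(any(f2$valid))

  b <- default_b_values()
  const_b <- image_series(array(250, c(2, 2, 12)), "b_value", b)
  f3 <- fit_adc_map(const_b, roi_mask(matrix(TRUE, 2, 2)))
  expect_equal(unname(f3$values[1, 1]), 0)

  rising <- image_series(array(rep(100 + b / 10, each = 4), c(2, 2, 12)),
                         "b_value", b)
  f4 <- fit_adc_map(rising, roi_mask(matrix(TRUE, 2, 2)))
  expect_false(any(f4$valid))
  expect_equal(unname(f4$values[1, 1]), 0)

  expect_error(fit_t1_map(image_series(array(1, c(2, 2, 2)),
                                       "repetition_time", c(100, 200)),
                          roi_mask(matrix(TRUE, 2, 2))), "frames")
  expect_error(fit_t1_map(const, roi_mask(matrix(FALSE, 2, 2))), "empty")
})

test_that("estimates are invariant to global intensity scaling", {
  tr <- make_phantom("hom", 6, c(32, 32), seed = 4)
  s <- simulate_t1_series(tr, noise_sd = 2, seed = 1)
  s_scaled <- s
  s_scaled$frames <- s$frames * 7.5
  a <- fit_t1_map(s, tr$tumor_mask)
  b <- fit_t1_map(s_scaled, tr$tumor_mask)
  expect_equal(a$values[a$valid & b$valid], b$values[a$valid & b$valid],
               tolerance = 1e-6)

  sd_ <- simulate_dwi_series(tr, noise_sd = 2, seed = 1)
  sd2 <- sd_; sd2$frames <- sd_$frames * 3
  expect_equal(fit_adc_map(sd_, tr$tumor_mask)$values,
               fit_adc_map(sd2, tr$tumor_mask)$values, tolerance = 1e-6)
})

test_that("fit error degrades monotonically with noise", {
  tr <- tiny_truth(t1 = 1500, n = 16)
  mask <- roi_mask(matrix(TRUE, 16, 16))
  meds <- vapply(c(0, 0.005, 0.01, 0.02), function(frac) {
    s <- simulate_t1_series(tr, noise_sd = frac * 500, seed = 21)
    f <- fit_t1_map(s, mask)
    stats::median(abs(f$values[f$valid] - 1500))
  }, 0)
  expect_true(all(diff(meds) >= 0))
})

test_that("delta-T1 maps subtract post from pre and propagate validity", {
  mk <- function(v, valid = TRUE) parameter_map(matrix(v, 2, 2), "T1", "ms",
                                                matrix(valid, 2, 2))
  d <- delta_t1_map(mk(2000), mk(1400))
  expect_true(all(d$values == 600))
  expect_equal(d$name, "deltaT1")

  same <- delta_t1_map(mk(1800), mk(1800))
  expect_true(all(same$values == 0))

  pre <- mk(2000); pre$valid[1, 1] <- FALSE
  d2 <- delta_t1_map(pre, mk(1500))
  expect_false(d2$valid[1, 1])
  expect_true(all(d2$valid[-1]))
  expect_true(is.na(d2$values[1, 1]))

  expect_error(delta_t1_map(mk(2000), parameter_map(matrix(1, 3, 3), "T1", "ms")),
               "mismatch")
  expect_error(delta_t1_map(mk(2000),
                            parameter_map(matrix(1, 2, 2), "T2", "ms")),
               "T1")
})
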