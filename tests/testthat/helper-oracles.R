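# Independent reference implementations used to cross-check the package's
# fitting and statistics routines. Deliberately brute-force and written
# without reuse of the package internals.

# Exhaustive 2-D grid search for the saturation-recovery model
# y = A + C * (1 - exp(-x / t1)): profile A, C linearly on a dense t1 grid.
grid_search_t1 <- function(x, y, t1_range = c(100, 5000), step = 0.1) {
  t1s <- seq(t1_range[1], t1_range[2], by = step)
  best <- c(Inf, NA, NA, NA)
  for (t1 in t1s) {
    f <- 1 - exp(-x / t1)
    fit <- stats::lm.fit(cbind(1, f), y)
    rss <- sum(fit$residuals^2)
    if (rss < best[1]) best <- c(rss, t1, fit$coefficients)
  }
  list(t1 = unname(best[2]), A = unname(best[3]),
       C = unname(best[4]), rss = unname(best[1]))
}

grid_search_t2 <- function(x, y, t2_range = c(5, 200), step = 0.01) {
  t2s <- seq(t2_range[1], t2_range[2], by = step)
  best <- c(Inf, NA)
  for (t2 in t2s) {
    f <- exp(-x / t2)
    rss <- sum(stats::lm.fit(cbind(1, f), y)$residuals^2)
    if (rss < best[1]) best <- c(rss, t2)
  }
  best[2]
}

# Log-linear closed form for S = S0 exp(-b * adc) (exact on noise-free data).
loglinear_adc <- function(b, y) {
  fit <- stats::lm.fit(cbind(1, b), log(y))
  unname(-fit$coefficients[2])
}

# Closed-form extended Tofts concentration for a biexponential AIF with
# onset: analytic convolution, no discretization.
analytic_tofts_biexp <- function(t_s, aif, timing, ktrans, ve, vp) {
  tau <- (t_s - timing$injection_time_s - aif$onset_delay_s) / 60
  k <- ktrans / ve
  comp <- function(ai, mi) {
    cpi <- aif$dose_scale_mM * ai * exp(-mi * pmax(tau, 0))
    conv <- aif$dose_scale_mM * ai *
      (exp(-mi * pmax(tau, 0)) - exp(-k * pmax(tau, 0))) / (k - mi)
    ifelse(tau < 0, 0, vp * cpi + ktrans * conv)
  }
  comp(aif$a1, aif$m1_per_min) + comp(aif$a2, aif$m2_per_min)
}

# Standard (vp-free) Tofts model via an independently coded scalar
# recursion over the same piecewise-linear plasma curve.
standard_tofts_scalar <- function(t_s, cp, ktrans, ve) {
  dt <- (t_s[2] - t_s[1]) / 60
  k <- ktrans / ve
  e <- exp(-k * dt)
  out <- numeric(length(t_s))
  acc <- 0
  for (i in 2:length(t_s)) {
    slope <- (cp[i] - cp[i - 1]) / dt
    i1 <- (1 - e) / k
    i2 <- (i1 - dt * e) / k
    acc <- acc * e + cp[i] * i1 - slope * i2
    out[i] <- ktrans * acc
  }
  out
}

# Exhaustive Mann-Whitney U enumeration: two-sided p over all label
# assignments (valid for small tie-free samples).
mwu_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  combs <- utils::combn(n, na)
  mu <- na * (n - na) / 2
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Direct summation formulas for the bias-corrected sample moments.
direct_skewness_g1 <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

direct_kurtosis_g2 <- function(x) {
  n <- length(x); m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m4 <- sum((x - m)^4) / n
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

# Dense grid-search oracle over (ktrans, ve) at fixed vp for the extended
# Tofts fit.
grid_search_tofts <- function(ct, cp, t_s, vp, kt_range, ve_range, n = 60) {
  kts <- seq(kt_range[1], kt_range[2], length.out = n)
  ves <- seq(ve_range[1], ve_range[2], length.out = n)
  best <- c(Inf, NA, NA)
  for (kt in kts) for (ve in ves) {
    pred <- phenomri::tofts_concentration(t_s, cp, kt, ve, vp)
    rss <- sum((ct - pred)^2)
    if (rss < best[1]) best <- c(rss, kt, ve)
  }
  list(ktrans = best[2], ve = best[3])
}

# Single-voxel phantom helper: smallest legal grid with uniform maps.
tiny_truth <- function(t1 = 1000, t2 = 40, adc = 1e-3, s0 = 500,
                       ktrans = 0.25, ve = 0.4, vp = 0.02, gd = 20,
                       n = 16) {
  truth <- make_phantom("homogeneous_nonmetastatic", 3,
                        grid_shape = c(n, n), seed = 1)
  all_true <- matrix(TRUE, n, n)
  set_map <- function(val, name, units)
    parameter_map(matrix(val, n, n), name, units, all_true)
  truth$t1_ms <- set_map(t1, "T1", "ms")
  truth$t2_ms <- set_map(t2, "T2", "ms")
  truth$adc_mm2_per_s <- set_map(adc, "ADC", "mm^2/s")
  truth$s0_au <- set_map(s0, "s0", "a.u.")
  truth$ktrans_per_min <- set_map(ktrans, "Ktrans", "1/min")
  truth$ve_frac <- set_map(ve, "ve", "fraction")
  truth$vp_frac <- set_map(vp, "vp", "fraction")
  truth$gd_ug_per_g <- set_map(gd, "Gd", "ug/g")
  truth
}
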