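# DCE-MRI: population AIF, signal<->concentration conversion, extended
# Tofts fitting and semi-quantitative curve metrics.

#' DCE acquisition timing
#'
#' Defaults follow a FLASH protocol with 610 repetitions over a 20 min
#' acquisition and contrast injection one minute after the scan start.
#'
#' @param n_frames number of dynamic frames (>= 10).
#' @param total_duration_s total scan duration in seconds.
#' @param injection_time_s bolus injection time in seconds
#'   (0 < injection < total).
#' @return an object of class `dce_timing`.
#' @export
dce_timing <- function(n_frames = 610, total_duration_s = 1200,
                       injection_time_s = 60) {
  if (n_frames < 10) stop("n_frames must be >= 10")
  if (!(injection_time_s > 0 && injection_time_s < total_duration_s))
    stop("injection_time_s must lie strictly inside the scan duration")
  structure(list(n_frames = as.integer(n_frames),
                 total_duration_s = total_duration_s,
                 injection_time_s = injection_time_s,
                 frame_interval_s = total_duration_s / n_frames),
            class = "dce_timing")
}

#' @rdname dce_timing
#' @param timing a `dce_timing`.
#' @return `frame_times()`: frame start times in seconds.
#' @export
frame_times <- function(timing) {
  (seq_len(timing$n_frames) - 1) * timing$frame_interval_s
}

#' Biexponential population arterial input function model
#'
#' `Cp(tau) = dose_scale * (a1 * exp(-m1 * tau) + a2 * exp(-m2 * tau))` with
#' `tau` the time since injection plus onset delay (minutes), and `Cp = 0`
#' before onset. A parametric stand-in for a measured murine population AIF;
#' all parameters are configurable study inputs.
#'
#' @param dose_scale_mM peak plasma concentration (mM).
#' @param a1,a2 amplitude fractions, must sum to 1.
#' @param m1_per_min,m2_per_min fast/slow decay rates (1/min), `m1 > m2 > 0`.
#' @param onset_delay_s delay between injection and arterial arrival (s).
#' @return an object of class `aif_model`.
#' @export
aif_model <- function(dose_scale_mM = 5, a1 = 0.8, m1_per_min = 3.0,
                      a2 = 0.2, m2_per_min = 0.06, onset_delay_s = 3) {
  if (abs(a1 + a2 - 1) > 1e-12) stop("a1 + a2 must equal 1")
  if (!(m1_per_min > m2_per_min && m2_per_min > 0))
    stop("decay rates must satisfy m1 > m2 > 0")
  structure(list(dose_scale_mM = dose_scale_mM, a1 = a1, a2 = a2,
                 m1_per_min = m1_per_min, m2_per_min = m2_per_min,
                 onset_delay_s = onset_delay_s),
            class = "aif_model")
}

#' Evaluate the population AIF on the scan time grid
#'
#' @param timing a [dce_timing()].
#' @param aif an [aif_model()].
#' @return a [concentration_curve()] of plasma concentration Cp (mM).
#' @export
population_aif <- function(timing, aif = aif_model()) {
  stopifnot(inherits(timing, "dce_timing"), inherits(aif, "aif_model"))
  t_s <- frame_times(timing)
  tau_min <- (t_s - timing$injection_time_s - aif$onset_delay_s) / 60
  cp <- ifelse(tau_min < 0, 0,
               aif$dose_scale_mM * (aif$a1 * exp(-aif$m1_per_min * tau_min) +
                                      aif$a2 * exp(-aif$m2_per_min * tau_min)))
  concentration_curve(t_s, cp, kind = "plasma concentration")
}

#' Signal-to-concentration conversion settings
#'
#' @param mode `"relaxivity"`: invert the spoiled-gradient-echo signal
#'   equation via the pre-contrast T1 map and contrast relaxivity, yielding
#'   concentration in mM (feeds Tofts fitting). `"relative"`: relative
#'   enhancement `(SI - SI0)/SI0` (feeds semi-quantitative metrics).
#' @param r1 longitudinal relaxivity (L mmol^-1 s^-1).
#' @param flip_angle_deg FLASH flip angle (degrees).
#' @param tr_ms FLASH repetition time (ms).
#' @return an object of class `dce_conversion`.
#' @export
dce_conversion <- function(mode = c("relaxivity", "relative"), r1 = 6.0,
                           flip_angle_deg = 30, tr_ms = 24.6) {
  mode <- match.arg(mode)
  structure(list(mode = mode, r1 = r1,
                 flip_angle_deg = flip_angle_deg, tr_ms = tr_ms),
            class = "dce_conversion")
}

# Spoiled gradient echo steady-state signal for R1 in 1/s.
spgr_signal <- function(r1_per_s, m0, conversion) {
  e1 <- exp(-(conversion$tr_ms / 1000) * r1_per_s)
  alpha <- conversion$flip_angle_deg * pi / 180
  m0 * sin(alpha) * (1 - e1) / (1 - cos(alpha) * e1)
}

# Exact convolution of a piecewise-linear Cp with exp(-k t) on a uniform
# grid (recursive exponential scheme). `k` may be a vector (one rate per
# voxel); returns an nt x length(k) matrix of integral values (conc * min).
exp_conv_uniform <- function(cp, dt_min, k) {
  nt <- length(cp)
  nk <- length(k)
  x <- k * dt_min
  small <- x < 1e-6
  e <- exp(-x)
  a1 <- ifelse(small, dt_min * (1 - x / 2 + x^2 / 6), (1 - e) / k)
  a2 <- ifelse(small, dt_min^2 * (0.5 - x / 3 + x^2 / 8), (a1 - dt_min * e) / k)
  out <- matrix(0, nt, nk)
  f <- numeric(nk)
  for (i in 2:nt) {
    s <- (cp[i] - cp[i - 1]) / dt_min
    f <- f * e + cp[i] * a1 - s * a2
    out[i, ] <- f
  }
  out
}

#' Extended Tofts tissue concentration
#'
#' `Ct(t) = vp * Cp(t) + Ktrans * int_0^t Cp(u) exp(-Ktrans (t - u) / ve) du`
#' evaluated exactly for the piecewise-linear plasma curve on a uniform
#' time grid.
#'
#' @param times_s uniform sample times (s).
#' @param cp plasma concentration at those times (mM).
#' @param ktrans volume transfer constant (1/min).
#' @param ve extravascular extracellular volume fraction (0 < ve <= 1).
#' @param vp plasma volume fraction.
#' @return tissue concentration (mM) at `times_s`.
#' @export
tofts_concentration <- function(times_s, cp, ktrans, ve, vp = 0) {
  drop(tofts_forward_matrix(times_s, cp, ktrans, ve, vp))
}

# Vectorized forward model over voxels: ktrans, ve, vp vectors of equal
# length N; returns nt x N matrix.
tofts_forward_matrix <- function(times_s, cp, ktrans, ve, vp) {
  stopifnot(length(cp) == length(times_s))
  dt_min <- diff(times_s[1:2]) / 60
  k <- ifelse(ktrans > 0, ktrans / pmax(ve, 1e-12), 1)  # k unused when ktrans=0
  conv <- exp_conv_uniform(cp, dt_min, k)
  sweep(conv, 2, ktrans, `*`) + outer(cp, vp)
}

#' Convert a dynamic signal series to concentration or enhancement
#'
#' Baseline signal `SI0` is the per-voxel mean over all frames strictly
#' before the injection time (at least 5 frames required). In
#' `"relative"` mode the result is `(SI - SI0)/SI0`; in `"relaxivity"` mode
#' the spoiled-gradient-echo signal equation is inverted using the
#' pre-contrast T1 and `C = (R1(t) - R1_0)/r1`.
#'
#' @param signal numeric matrix (frames x voxels) or vector (one curve).
#' @param timing a [dce_timing()].
#' @param t1_0_ms pre-contrast T1 per voxel (ms); required in relaxivity
#'   mode (scalar or one value per voxel).
#' @param conversion a [dce_conversion()].
#' @return list with `times_s`, `values` (frames x voxels matrix),
#'   `valid` (per-voxel flag; FALSE where SI0 <= 0 or inversion left the
#'   physical signal range) and `mode`.
#' @export
signal_to_concentration <- function(signal, timing, t1_0_ms = NULL,
                                    conversion = dce_conversion()) {
  stopifnot(inherits(timing, "dce_timing"))
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1)
  t_s <- frame_times(timing)
  if (nrow(signal) != length(t_s))
    stop("signal must have one row per dynamic frame")
  pre <- t_s < timing$injection_time_s
  if (sum(pre) < 5) stop("need at least 5 baseline frames before injection")
  si0 <- colMeans(signal[pre, , drop = FALSE])
  valid <- si0 > 0
  if (conversion$mode == "relative") {
    vals <- sweep(sweep(signal, 2, si0, `-`), 2, pmax(si0, .Machine$double.eps), `/`)
    vals[, !valid] <- NA_real_
    return(list(times_s = t_s, values = vals, valid = valid,
                mode = "relative"))
  }
  if (is.null(t1_0_ms)) stop("relaxivity mode requires the pre-contrast T1")
  t1_0 <- rep_len(as.vector(t1_0_ms), ncol(signal))
  tr_s <- conversion$tr_ms / 1000
  cosa <- cos(conversion$flip_angle_deg * pi / 180)
  r1_0 <- 1000 / t1_0
  e10 <- exp(-tr_s * r1_0)
  g0 <- (1 - e10) / (1 - cosa * e10)
  msin <- si0 / g0                       # M0 * sin(alpha), per voxel
  gt <- sweep(signal, 2, pmax(msin, .Machine$double.eps), `/`)
  e1 <- (1 - gt) / (1 - cosa * gt)
  bad <- !(e1 > 0 & e1 < 1)
  e1[bad] <- NA_real_
  r1_t <- -log(e1) / tr_s
  vals <- sweep(r1_t, 2, r1_0, `-`) / conversion$r1
  valid <- valid & colSums(bad) == 0
  list(times_s = t_s, values = vals, valid = valid, mode = "relaxivity")
}

#' ROI-mean dynamic curve
#'
#' Per-frame mean signal over the masked voxels of a dynamic series.
#'
#' @param series an [image_series()] along `dynamic_time`.
#' @param mask an [roi_mask()].
#' @param timing optional [dce_timing()] (defaults to the series axis).
#' @return a [concentration_curve()] holding the mean signal.
#' @export
roi_curve <- function(series, mask, timing = NULL) {
  stopifnot(inherits(series, "image_series"))
  check_mask(mask, dim(series$frames))
  idx <- which(mask$grid)
  flat <- matrix(series$frames, prod(dim(series$frames)[1:2]),
                 dim(series$frames)[3])
  vals <- colMeans(flat[idx, , drop = FALSE])
  t_s <- if (is.null(timing)) series$axis_values else frame_times(timing)
  concentration_curve(t_s, vals, kind = "ROI mean signal")
}

#' Extended Tofts fit configuration
#'
#' @param ktrans_bounds,ve_bounds,vp_bounds box constraints for the three
#'   parameters (1/min and fractions). `ve + vp <= 1` is enforced with a
#'   quadratic penalty.
#' @param k_grid_points number of log-spaced rate candidates in the
#'   variable-projection search.
#' @param polish run a final bounded quasi-Newton refinement.
#' @return an object of class `tofts_fit_config`.
#' @export
tofts_fit_config <- function(ktrans_bounds = c(0, 5), ve_bounds = c(0.01, 1),
                             vp_bounds = c(0, 0.2), k_grid_points = 61,
                             polish = TRUE) {
  structure(list(ktrans_bounds = ktrans_bounds, ve_bounds = ve_bounds,
                 vp_bounds = vp_bounds, k_grid_points = k_grid_points,
                 polish = polish),
            class = "tofts_fit_config")
}

# Nonnegative 2-parameter LS of ct ~ ktrans * b2 + vp * b1; returns
# c(ktrans, vp, rss). Columns of cbind(b2, b1) assumed nonzero.
nnls2 <- function(ct, b1, b2) {
  s11 <- sum(b2 * b2); s12 <- sum(b2 * b1); s22 <- sum(b1 * b1)
  y1 <- sum(b2 * ct); y2 <- sum(b1 * ct)
  det <- s11 * s22 - s12 * s12
  if (det > 1e-300) {
    kt <- (y1 * s22 - y2 * s12) / det
    vp <- (y2 * s11 - y1 * s12) / det
  } else {
    kt <- if (s11 > 0) y1 / s11 else 0
    vp <- 0
  }
  if (kt < 0) { kt <- 0; vp <- if (s22 > 0) max(y2 / s22, 0) else 0 }
  if (vp < 0) { vp <- 0; kt <- if (s11 > 0) max(y1 / s11, 0) else 0 }
  rss <- sum((ct - kt * b2 - vp * b1)^2)
  c(kt, vp, rss)
}

#' Fit the extended Tofts model to a tissue concentration curve
#'
#' Minimizes the squared error of `Ct(t) = vp Cp(t) + Ktrans (Cp * exp)(t)`
#' over bounded `(Ktrans, ve, vp)`. The search exploits that for a fixed
#' elimination rate `k = Ktrans/ve` the model is linear in `(Ktrans, vp)`:
#' a log-spaced grid over `k` with nonnegative least squares per candidate,
#' golden-section refinement of `k`, and an optional bounded quasi-Newton
#' polish. The convolution is evaluated by the exact recursive exponential
#' scheme on the uniform frame grid.
#'
#' @param ct tissue concentration: a [concentration_curve()] or numeric
#'   vector (mM).
#' @param cp plasma concentration on the same time grid.
#' @param times_s sample times if `ct`/`cp` are plain vectors.
#' @param config a [tofts_fit_config()].
#' @return an object of class `pk_params`: `ktrans_per_min`, `ve_frac`,
#'   `vp_frac`, `rmse`, `degenerate`.
#' @export
fit_extended_tofts <- function(ct, cp, times_s = NULL,
                               config = tofts_fit_config()) {
  if (inherits(ct, "concentration_curve")) { times_s <- ct$times_s; ct <- ct$values }
  if (inherits(cp, "concentration_curve")) {
    if (!is.null(times_s) && length(cp$values) != length(ct))
      stop("ct and cp must share one time grid")
    times_s <- times_s %||% cp$times_s; cp <- cp$values
  }
  if (is.null(times_s)) stop("times_s required when curves are plain vectors")
  if (length(ct) != length(cp) || length(ct) != length(times_s))
    stop("ct and cp must share one time grid")
  if (length(ct) < 20) stop("need at least 20 samples for a Tofts fit")

  if (max(abs(ct)) < 1e-12 || max(cp) <= 0) {
    return(structure(list(ktrans_per_min = 0, ve_frac = NA_real_,
                          vp_frac = 0, rmse = 0, degenerate = TRUE),
                     class = "pk_params"))
  }
  dt_min <- diff(times_s[1:2]) / 60
  kb <- config$ktrans_bounds; veb <- config$ve_bounds; vpb <- config$vp_bounds

  k_grid <- exp(seq(log(1e-3), log(1e3), length.out = config$k_grid_points))
  basis <- exp_conv_uniform(cp, dt_min, k_grid)       # nt x nk
  rss_of_k <- function(kvec) {
    b <- exp_conv_uniform(cp, dt_min, kvec)
    vapply(seq_along(kvec), function(j) nnls2(ct, cp, b[, j])[3], 0)
  }
  rss_grid <- vapply(seq_along(k_grid),
                     function(j) nnls2(ct, cp, basis[, j])[3], 0)
  j <- which.min(rss_grid)
  lo <- k_grid[max(j - 1, 1)]; hi <- k_grid[min(j + 1, length(k_grid))]
  # golden-section on log k
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- rss_of_k(exp(x1)); f2 <- rss_of_k(exp(x2))
  for (it in 1:40) {
    if (f1 < f2) { b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- rss_of_k(exp(x1))
    } else { a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- rss_of_k(exp(x2)) }
  }
  k_hat <- exp((a + b) / 2)
  sol <- nnls2(ct, cp, exp_conv_uniform(cp, dt_min, k_hat)[, 1])
  ktrans <- sol[1]; vp <- sol[2]
  ve <- if (ktrans > 0) ktrans / k_hat else NA_real_

  par0 <- c(min(max(ktrans, kb[1]), kb[2]),
            min(max(ifelse(is.na(ve), veb[1], ve), veb[1]), veb[2]),
            min(max(vp, vpb[1]), vpb[2]))
  # the profiled search already solves the unconstrained LS problem
  # exactly; a bounded polish is only needed when its solution had to be
  # projected onto the constraint box
  interior <- ktrans > 1e-10 && !is.na(ve) &&
    isTRUE(all.equal(par0, c(ktrans, ve, vp), tolerance = 1e-12)) &&
    ve + vp <= 1
  if (isTRUE(config$polish) && ktrans > 1e-10 && !interior) {
    obj <- function(p) {
      pred <- tofts_concentration(times_s, cp, p[1], p[2], p[3])
      sum((ct - pred)^2) + 1e6 * max(0, p[2] + p[3] - 1)^2
    }
    fit <- stats::optim(par0, obj, method = "L-BFGS-B",
                        lower = c(kb[1], veb[1], vpb[1]),
                        upper = c(kb[2], veb[2], vpb[2]),
                        control = list(factr = 10, maxit = 500))
    if (fit$value <= obj(par0) + 1e-15) {
      ktrans <- fit$par[1]; ve <- fit$par[2]; vp <- fit$par[3]
    }
  }
  pred <- if (ktrans > 1e-10)
    tofts_concentration(times_s, cp, ktrans, ve, vp)
  else vp * cp
  if (ktrans <= 1e-10) ve <- NA_real_
  structure(list(ktrans_per_min = ktrans, ve_frac = ve, vp_frac = vp,
                 rmse = sqrt(mean((ct - pred)^2)), degenerate = FALSE),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> Ktrans %.4g /min, ve %.3g, vp %.3g (rmse %.3g%s)\n",
              x$ktrans_per_min, x$ve_frac, x$vp_frac, x$rmse,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Voxel-wise extended Tofts parameter maps
#'
#' Runs the same variable-projection search as [fit_extended_tofts()]
#' simultaneously over all masked voxels (shared k-grid, vectorized
#' golden-section refinement; no per-voxel polish).
#'
#' @param conc frames x voxels concentration matrix (e.g. from
#'   [signal_to_concentration()]), or a list as returned by it.
#' @param times_s frame times (s); taken from `conc` if it is a list.
#' @param mask an [roi_mask()] selecting voxels; required when `conc` is a
#'   full-grid list.
#' @param cp plasma concentration curve ([concentration_curve()] or vector).
#' @param config a [tofts_fit_config()].
#' @return list of three [parameter_map()]s: `ktrans`, `ve`, `vp`.
#' @export
fit_dce_map <- function(conc, cp, mask, times_s = NULL,
                        config = tofts_fit_config()) {
  if (inherits(cp, "concentration_curve")) { times_s <- times_s %||% cp$times_s; cp <- cp$values }
  if (is.list(conc) && !is.null(conc$values)) {
    times_s <- times_s %||% conc$times_s
    conc <- conc$values
  }
  check_mask(mask, NULL)
  idx <- which(mask$grid)
  if (ncol(conc) == length(mask$grid)) conc <- conc[, idx, drop = FALSE]
  stopifnot(ncol(conc) == length(idx), nrow(conc) == length(times_s))
  dt_min <- diff(times_s[1:2]) / 60
  nvox <- ncol(conc)
  ok <- colSums(!is.finite(conc)) == 0 & apply(conc, 2, function(x) max(abs(x))) > 1e-12
  k_grid <- exp(seq(log(1e-3), log(1e3), length.out = config$k_grid_points))
  basis <- exp_conv_uniform(cp, dt_min, k_grid)
  best_rss <- rep(Inf, nvox); best_j <- rep(1L, nvox)
  s22 <- sum(cp * cp)
  for (j in seq_along(k_grid)) {
    b2 <- basis[, j]
    s11 <- sum(b2 * b2); s12 <- sum(b2 * cp)
    y1 <- crossprod(b2, conc)[1, ]; y2 <- crossprod(cp, conc)[1, ]
    det <- s11 * s22 - s12^2
    kt <- (y1 * s22 - y2 * s12) / det
    vp <- (y2 * s11 - y1 * s12) / det
    neg_k <- kt < 0; neg_v <- vp < 0
    kt[neg_k] <- 0; vp[neg_k] <- pmax(y2[neg_k] / s22, 0)
    vp[neg_v & !neg_k] <- 0
    kt[neg_v & !neg_k] <- pmax(y1[neg_v & !neg_k] / s11, 0)
    syy <- colSums(conc^2)
    rss <- syy - 2 * (kt * y1 + vp * y2) + kt^2 * s11 + vp^2 * s22 +
      2 * kt * vp * s12
    upd <- ok & rss < best_rss
    best_rss[upd] <- rss[upd]; best_j[upd] <- j
  }
  # vectorized golden refinement on log k within the bracketing interval
  a <- log(k_grid[pmax(best_j - 1L, 1L)])
  b <- log(k_grid[pmin(best_j + 1L, length(k_grid))])
  rss_at <- function(kvec) {
    bmat <- exp_conv_uniform(cp, dt_min, kvec)
    vapply(seq_len(nvox), function(v) nnls2(conc[, v], cp, bmat[, v])[3], 0)
  }
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- rss_at(exp(x1)); f2 <- rss_at(exp(x2))
  for (it in 1:40) {
    m <- f1 < f2
    b[m] <- x2[m]; x2[m] <- x1[m]; f2[m] <- f1[m]
    x1[m] <- b[m] - gr * (b[m] - a[m])
    a[!m] <- x1[!m]; x1[!m] <- x2[!m]; f1[!m] <- f2[!m]
    x2[!m] <- a[!m] + gr * (b[!m] - a[!m])
    fn <- rss_at(exp(ifelse(m, x1, x2)))
    f1[m] <- fn[m]; f2[!m] <- fn[!m]
  }
  k_hat <- exp((a + b) / 2)
  bmat <- exp_conv_uniform(cp, dt_min, k_hat)
  kt <- vp <- ve <- rmse <- rep(NA_real_, nvox)
  for (v in seq_len(nvox)) {
    if (!ok[v]) { kt[v] <- 0; vp[v] <- 0; next }
    s <- nnls2(conc[, v], cp, bmat[, v])
    kt[v] <- s[1]; vp[v] <- s[2]
    ve[v] <- if (s[1] > 0) min(s[1] / k_hat[v], 1) else NA_real_
    rmse[v] <- sqrt(s[3] / nrow(conc))
  }
  dims <- dim(mask$grid)
  to_map <- function(x, name, units) {
    m <- matrix(NA_real_, dims[1], dims[2]); m[idx] <- x
    vld <- matrix(FALSE, dims[1], dims[2]); vld[idx] <- ok & is.finite(x)
    parameter_map(m, name, units, vld)
  }
  list(ktrans = to_map(kt, "Ktrans", "1/min"),
       ve = to_map(ve, "ve", "fraction"),
       vp = to_map(vp, "vp", "fraction"))
}

#' Semi-quantitative DCE curve metrics
#'
#' Peak enhancement (maximum post-injection value), maximum slope (largest
#' forward finite difference of the moving-average-smoothed curve, per
#' minute) and area under the curve (trapezoidal integral from injection to
#' scan end, enhancement x minutes).
#'
#' @param enhancement a [concentration_curve()] (or numeric vector) of
#'   relative enhancement on the full scan grid.
#' @param timing a [dce_timing()].
#' @param smooth_window moving-average width in frames (odd; 1 = none).
#' @return an object of class `semiquant_metrics` with `peak_enhancement`,
#'   `slope_max` and `auc`.
#' @export
semiquant_metrics <- function(enhancement, timing, smooth_window = 3) {
  e <- if (inherits(enhancement, "concentration_curve")) enhancement$values else enhancement
  t_s <- if (inherits(enhancement, "concentration_curve")) enhancement$times_s else frame_times(timing)
  if (smooth_window > length(e))
    stop("smooth_window larger than the number of frames")
  post <- t_s >= timing$injection_time_s
  peak <- max(e[post])
  sm <- if (smooth_window > 1)
    stats::filter(e, rep(1 / smooth_window, smooth_window), sides = 2)
  else e
  sm <- as.numeric(sm)
  keep <- !is.na(sm)
  dt_min <- diff(t_s[1:2]) / 60
  slope <- max(diff(sm[keep]) / dt_min)
  # integrate from the injection instant (linear interpolation at t_inj)
  ti <- timing$injection_time_s
  tt <- c(ti, t_s[t_s > ti])
  ee <- c(stats::approx(t_s, e, xout = ti)$y, e[t_s > ti])
  auc <- trapz(tt / 60, ee)
  structure(list(peak_enhancement = peak, slope_max = slope, auc = auc),
            class = "semiquant_metrics")
}

#' @export
print.semiquant_metrics <- function(x, ...) {
  cat(sprintf("<semiquant_metrics> peak %.4g, slope_max %.4g /min, AUC %.4g min\n",
              x$peak_enhancement, x$slope_max, x$auc))
  invisible(x)
}
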