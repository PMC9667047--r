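# Voxel-wise mono-exponential parameter mapping (T1, T2, ADC) and delta-T1
# contrast-retention maps.
#
# All three models are separable: for a fixed relaxation/diffusion constant
# the amplitude parameters enter linearly. Fitting therefore reduces to a
# 1-D search over the nonlinear constant with the amplitudes profiled out
# (variable projection): a coarse candidate grid shared across voxels picks
# a bracket, then a vectorized golden-section refinement drives every voxel
# to its own minimum simultaneously. The procedure is deterministic,
# derivative-free and immune to starting-value choices.

#' Fit configuration for relaxometry and diffusion mapping
#'
#' @param bounds list of per-parameter search intervals: `t1`, `t2` (ms)
#'   and `adc` (mm^2/s). A voxel whose estimate lands on a bound is marked
#'   invalid rather than silently clipped.
#' @param grid_points coarse candidate grid size for bracketing.
#' @param max_iterations golden-section refinement iterations (each shrinks
#'   the bracket by the golden ratio; 36 iterations refine the coarse-grid
#'   bracket to ~1e-8 relative precision).
#' @param tolerance relative tolerance used when flagging bound hits.
#' @param min_snr_exclude optional: drop frames whose ROI-median signal
#'   falls below this multiple of the smallest frame median (high-b noise
#'   floor guard); `NULL` disables.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(t1 = c(1, 10000), t2 = c(1, 1000),
                                     adc = c(0, 5e-3)),
                       grid_points = 64, max_iterations = 36,
                       tolerance = 1e-6, min_snr_exclude = NULL) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  for (b in bounds) if (length(b) != 2 || b[2] <= b[1])
    stop("each bound must be a nonempty interval")
  structure(list(bounds = bounds, grid_points = as.integer(grid_points),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, min_snr_exclude = min_snr_exclude),
            class = "fit_config")
}

# Profiled RSS for the affine model y ~ A + C * f(x) evaluated per voxel.
# F is either an n_t x N basis matrix (one column per voxel) or a single
# n_t vector shared by all voxels. Returns list(A, C, rss).
affine_profile <- function(F, Y, sums) {
  nt <- nrow(Y); N <- ncol(Y)
  if (is.matrix(F)) {
    sf <- .colSums(F, nt, N); sff <- .colSums(F * F, nt, N)
    sfy <- .colSums(F * Y, nt, N)
  } else {
    sf <- sum(F); sff <- sum(F * F)
    sfy <- as.vector(crossprod(F, Y))
  }
  det <- nt * sff - sf^2
  singular <- det <= 1e-12 * (nt * sff + sf^2)
  det[singular] <- NA_real_
  C <- (nt * sfy - sf * sums$sy) / det
  A <- (sums$sy - C * sf) / nt
  rss <- sums$syy - A * sums$sy - C * sfy
  rss[singular] <- Inf
  list(A = A, C = C, rss = pmax(rss, 0))
}

# Profiled RSS for the scale model y ~ C * f(x).
scale_profile <- function(F, Y, sums) {
  nt <- nrow(Y); N <- ncol(Y)
  if (is.matrix(F)) {
    sff <- .colSums(F * F, nt, N)
    sfy <- .colSums(F * Y, nt, N)
  } else {
    sff <- rep(sum(F * F), N)
    sfy <- as.vector(crossprod(F, Y))
  }
  C <- ifelse(sff > 0, sfy / sff, 0)
  rss <- sums$syy - C * sfy
  list(C = C, rss = pmax(rss, 0))
}

# Vectorized golden-section minimization of a per-voxel 1-D profiled RSS.
# rss_fn(x) takes a per-voxel parameter vector and returns the RSS vector.
golden_refine <- function(rss_fn, lo, hi, iterations) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- rss_fn(x1); f2 <- rss_fn(x2)
  for (i in seq_len(iterations)) {
    m <- f1 < f2
    b[m] <- x2[m]; x2[m] <- x1[m]; f2[m] <- f1[m]
    x1[m] <- b[m] - gr * (b[m] - a[m])
    a[!m] <- x1[!m]; x1[!m] <- x2[!m]; f1[!m] <- f2[!m]
    x2[!m] <- a[!m] + gr * (b[!m] - a[!m])
    fn <- rss_fn(ifelse(m, x1, x2))
    f1[m] <- fn[m]; f2[!m] <- fn[!m]
  }
  (a + b) / 2
}

# Shared driver: 1-D separable exponential fit over all masked voxels.
# basis_fn(theta) returns an n_t vector for scalar theta and the n_t x N
# basis matrix for a per-voxel vector; profile is affine_profile or
# scale_profile; the refinement searches on transform(theta).
separable_fit <- function(Y, theta_grid, basis_fn, profile, iterations,
                          log_search = TRUE) {
  N <- ncol(Y)
  sums <- list(sy = .colSums(Y, nrow(Y), N), syy = .colSums(Y * Y, nrow(Y), N))
  best <- rep(Inf, N); besti <- rep(1L, N)
  for (i in seq_along(theta_grid)) {
    r <- profile(basis_fn(theta_grid[i]), Y, sums)$rss
    upd <- r < best
    best[upd] <- r[upd]; besti[upd] <- i
  }
  lo <- theta_grid[pmax(besti - 1L, 1L)]
  hi <- theta_grid[pmin(besti + 1L, length(theta_grid))]
  tf <- if (log_search) log else identity
  itf <- if (log_search) exp else identity
  rss_fn <- function(x) profile(basis_fn(itf(x)), Y, sums)$rss
  theta <- itf(golden_refine(rss_fn, tf(lo), tf(hi), iterations))
  fin <- profile(basis_fn(theta), Y, sums)
  list(theta = theta, fit = fin, sums = sums)
}

prepare_fit <- function(series, mask, axis_kind, min_frames) {
  stopifnot(inherits(series, "image_series"))
  if (series$axis_kind != axis_kind)
    stop(sprintf("series axis must be '%s'", axis_kind))
  nf <- dim(series$frames)[3]
  if (nf < min_frames)
    stop(sprintf("need at least %d frames, got %d", min_frames, nf))
  check_mask(mask, dim(series$frames))
  idx <- which(mask$grid)
  flat <- matrix(series$frames, prod(dim(series$frames)[1:2]), nf)
  list(Y = t(flat[idx, , drop = FALSE]), idx = idx,
       x = series$axis_values, dims = dim(series$frames)[1:2])
}

assemble_map <- function(res, prep, name, units, valid) {
  valid[is.na(valid)] <- FALSE
  dims <- prep$dims
  vals <- matrix(NA_real_, dims[1], dims[2])
  vld <- matrix(FALSE, dims[1], dims[2])
  rmse <- matrix(NA_real_, dims[1], dims[2])
  vals[prep$idx] <- res$theta
  vld[prep$idx] <- valid
  rmse[prep$idx] <- sqrt(res$fit$rss / nrow(prep$Y))
  parameter_map(vals, name, units, vld, rmse)
}

near_bound <- function(theta, bounds, tol) {
  theta <= bounds[1] * (1 + tol) + tol * diff(bounds) * 1e-6 |
    theta >= bounds[2] * (1 - tol)
}

#' Voxel-wise T1 map from a variable-TR series
#'
#' Fits the saturation-recovery signal model
#' `SI(TR) = A + C * (1 - exp(-TR/T1))` per masked voxel by separable
#' nonlinear least squares (offset `A` and amplitude `C` profiled out,
#' golden-section search over T1 within bounds). Voxels where the fit
#' degenerates (non-positive amplitude, constant signal or a bound hit)
#' are marked invalid.
#'
#' @param series an [image_series()] along `repetition_time` (>= 3 frames).
#' @param mask an [roi_mask()].
#' @param config a [fit_config()].
#' @return a [parameter_map()] named `"T1"` in ms, with validity mask and
#'   per-voxel fit RMSE.
#' @export
fit_t1_map <- function(series, mask, config = fit_config()) {
  prep <- prepare_fit(series, mask, "repetition_time", 3L)
  bounds <- config$bounds$t1
  grid <- exp(seq(log(bounds[1]), log(bounds[2]),
                  length.out = config$grid_points))
  basis_fn <- function(t1) {
    m <- 1 - exp(outer(prep$x, -1 / t1))
    if (length(t1) == 1L) drop(m) else m
  }
  res <- separable_fit(prep$Y, grid, basis_fn, affine_profile,
                       config$max_iterations)
  sdY <- apply(prep$Y, 2, stats::sd)
  valid <- is.finite(res$theta) & res$fit$C > config$tolerance * sdY &
    sdY > 0 & !near_bound(res$theta, bounds, config$tolerance)
  assemble_map(res, prep, "T1", "ms", valid)
}

#' Voxel-wise T2 map from a multi-echo series
#'
#' Fits `SI(TE) = A + C * exp(-TE/T2)` per masked voxel; same separable
#' least-squares engine and validity rules as [fit_t1_map()].
#'
#' @inheritParams fit_t1_map
#' @param series an [image_series()] along `echo_time` (>= 3 frames).
#' @return a [parameter_map()] named `"T2"` in ms.
#' @export
fit_t2_map <- function(series, mask, config = fit_config()) {
  prep <- prepare_fit(series, mask, "echo_time", 3L)
  bounds <- config$bounds$t2
  grid <- exp(seq(log(bounds[1]), log(bounds[2]),
                  length.out = config$grid_points))
  basis_fn <- function(t2) {
    m <- exp(outer(prep$x, -1 / t2))
    if (length(t2) == 1L) drop(m) else m
  }
  res <- separable_fit(prep$Y, grid, basis_fn, affine_profile,
                       config$max_iterations)
  sdY <- apply(prep$Y, 2, stats::sd)
  valid <- is.finite(res$theta) & res$fit$C > config$tolerance * sdY &
    sdY > 0 & !near_bound(res$theta, bounds, config$tolerance)
  assemble_map(res, prep, "T2", "ms", valid)
}

#' Voxel-wise ADC map from a multi-b diffusion series
#'
#' Fits the mono-exponential decay `S(b) = S0 * exp(-b * ADC)` per masked
#' voxel over all b-values in one fit. A constant signal yields ADC = 0
#' (free diffusion absent); a signal that increases with b is non-physical
#' and the voxel is marked invalid with ADC clipped at 0.
#'
#' @inheritParams fit_t1_map
#' @param series an [image_series()] along `b_value` (>= 2 frames).
#' @return a [parameter_map()] named `"ADC"` in mm^2/s.
#' @export
fit_adc_map <- function(series, mask, config = fit_config()) {
  prep <- prepare_fit(series, mask, "b_value", 2L)
  if (!is.null(config$min_snr_exclude)) {
    med <- apply(prep$Y, 1, stats::median)
    keep <- med >= config$min_snr_exclude * max(med)
    if (sum(keep) >= 2) { prep$Y <- prep$Y[keep, , drop = FALSE]; prep$x <- prep$x[keep] }
  }
  bounds <- config$bounds$adc
  grid <- seq(bounds[1], bounds[2], length.out = config$grid_points)
  basis_fn <- function(d) {
    m <- exp(outer(prep$x, -d))
    if (length(d) == 1L) drop(m) else m
  }
  res <- separable_fit(prep$Y, grid, basis_fn, scale_profile,
                       config$max_iterations, log_search = FALSE)
  # direction of the decay: weighted log-linear slope sign per voxel
  dirn <- apply(prep$Y, 2, function(y) {
    if (all(y > 0)) stats::cov(prep$x, log(y)) else stats::cov(prep$x, y)
  })
  at_zero <- res$theta <= bounds[1] + 1e-15
  res$theta[at_zero] <- 0
  sdY <- apply(prep$Y, 2, stats::sd)
  increasing <- dirn > 0 & sdY > config$tolerance * pmax(colMeans(prep$Y), 1e-12)
  valid <- is.finite(res$theta) & res$fit$C > 0 & !increasing &
    res$theta < bounds[2] * (1 - config$tolerance)
  assemble_map(res, prep, "ADC", "mm^2/s", valid)
}

#' Contrast-retention delta-T1 map
#'
#' `deltaT1 = T1_pre - T1_post` per voxel: positive where the retained
#' contrast agent shortens T1. Valid only where both inputs are valid.
#'
#' @param pre_map,post_map [parameter_map()]s named `"T1"` on identical
#'   grids.
#' @return a [parameter_map()] named `"deltaT1"` in ms.
#' @export
delta_t1_map <- function(pre_map, post_map) {
  stopifnot(inherits(pre_map, "parameter_map"),
            inherits(post_map, "parameter_map"))
  if (pre_map$name != "T1" || post_map$name != "T1")
    stop("both inputs must be T1 maps")
  if (!identical(dim(pre_map$values), dim(post_map$values)))
    stop("T1 maps have mismatched grids")
  vals <- pre_map$values - post_map$values
  valid <- pre_map$valid & post_map$valid
  vals[!valid] <- NA_real_
  parameter_map(vals, "deltaT1", "ms", valid)
}
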