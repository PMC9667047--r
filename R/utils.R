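# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Every stochastic operation in the package draws its RNG state from a seed
#' derived from the master seed and a short stream label, so that adding or
#' reordering simulated series does not perturb the noise of the others.
#' The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (single integer).
#' @param stream character label naming the random stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stream))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Smooth random field on an nr x nc grid: coarse iid normals, bilinearly
# interpolated. Amplitude 1 (approx unit sd at the knots). Draws from the
# current RNG state.
smooth_field <- function(nr, nc, coarse = 6L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  # knot positions spanning the grid
  rk <- seq(1, nr, length.out = coarse)
  ck <- seq(1, nc, length.out = coarse)
  # bilinear interpolation, vectorized per axis
  interp_axis <- function(knots, n) {
    x <- seq_len(n)
    i <- findInterval(x, knots, all.inside = TRUE)
    w <- (x - knots[i]) / (knots[i + 1] - knots[i])
    list(i = i, w = w)
  }
  ri <- interp_axis(rk, nr)
  ci <- interp_axis(ck, nc)
  a <- g[ri$i, ci$i]
  b <- g[ri$i + 1L, ci$i]
  cc <- g[ri$i, ci$i + 1L]
  d <- g[ri$i + 1L, ci$i + 1L]
  wr <- matrix(ri$w, nr, nc)
  wc <- matrix(ci$w, nr, nc, byrow = TRUE)
  (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b + (1 - wr) * wc * cc + wr * wc * d
}

# Trapezoidal integral of y(x) on an increasing grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
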