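# LA-ICP-MS quantification: external calibration on gelatin standards,
# 3-sigma/10-sigma detection limits, line-scan quantification, summaries.

#' Fit an external calibration curve by weighted linear regression
#'
#' Regresses the per-level mean line intensity on the nominal concentration
#' with weights `1/s_i^2` from the replicate variance at each level (pooled
#' replicate variance substituted where a level has zero scatter; ordinary
#' least squares when all levels are noise-free). Standards are prepared in
#' mg/L; tissue concentrations are reported in ug/g assuming unit density,
#' so the two unit scales coincide numerically.
#'
#' @param standards data.frame with columns `concentration` and `intensity`
#'   (one row per ablated replicate line), at least 3 distinct levels
#'   including a blank (0) with >= 2 replicates each.
#' @param element element label carried through to the curve.
#' @return an object of class `calibration_curve`: `slope`, `intercept`,
#'   `weights`, `r_squared`, `sigma_blank`, `lod`, `loq`, `element`,
#'   `valid`.
#' @export
fit_calibration <- function(standards, element = "Gd") {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "intensity") %in% names(standards)))
  if (any(standards$concentration < 0) || any(standards$intensity < 0))
    stop("concentrations and intensities must be >= 0")
  levels_ <- sort(unique(standards$concentration))
  if (length(levels_) < 3) stop("need at least 3 distinct calibration levels")
  if (!any(levels_ == 0)) stop("calibration must include a blank (0) level")
  agg <- do.call(rbind, lapply(levels_, function(lv) {
    x <- standards$intensity[standards$concentration == lv]
    if (length(x) < 2) stop("each level needs >= 2 replicate intensities")
    data.frame(concentration = lv, mean = mean(x), sd = stats::sd(x),
               n = length(x))
  }))
  s2 <- agg$sd^2
  if (any(s2 == 0)) {
    pooled <- sum((agg$n - 1) * s2) / sum(agg$n - 1)
    s2 <- if (pooled > 0) ifelse(s2 == 0, pooled, s2) else rep(1, length(s2))
  }
  w <- 1 / s2
  fit <- stats::lm(mean ~ concentration, data = agg, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope)) stop("calibration levels are degenerate")
  sigma_blank <- agg$sd[agg$concentration == 0]
  valid <- slope > 0
  lod <- if (valid) 3 * sigma_blank / slope else NA_real_
  loq <- if (valid) 10 * sigma_blank / slope else NA_real_
  tss <- sum(w * (agg$mean - stats::weighted.mean(agg$mean, w))^2)
  r_squared <- if (tss > 0) 1 - sum(w * stats::residuals(fit)^2) / tss else 1
  structure(list(slope = slope, intercept = intercept, weights = w,
                 r_squared = r_squared,
                 sigma_blank = sigma_blank, lod = lod, loq = loq,
                 element = element, valid = valid, levels = agg),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: slope %.4g counts/(ug/g), intercept %.4g, R^2 %.5f\n",
              x$element, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  LOD %.4g ug/g, LOQ %.4g ug/g%s\n", x$lod, x$loq,
              if (!x$valid) " [INVALID: nonpositive slope]" else ""))
  invisible(x)
}

#' Detection and quantification limits of a calibration curve
#'
#' `LOD = 3 sigma_blank / slope`, `LOQ = 10 sigma_blank / slope`, with
#' `sigma_blank` the replicate standard deviation at the blank level, so
#' `LOQ / LOD = 10/3` identically.
#'
#' @param curve a [calibration_curve][fit_calibration].
#' @return named numeric `c(lod = , loq = )` in ug/g.
#' @export
compute_lod_loq <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!(curve$slope > 0)) stop("LOD/LOQ require a positive calibration slope")
  c(lod = 3 * curve$sigma_blank / curve$slope,
    loq = 10 * curve$sigma_blank / curve$slope)
}

#' Quantify line-scan intensities into an elemental concentration map
#'
#' Applies `(intensity - intercept) / slope` per laser spot and stacks the
#' ablation lines into a 2D map at the spot spacing. Values below the LOD
#' are reported as-is but flagged `sub_lod`; negative concentrations are
#' retained (unbiased estimates).
#'
#' @param linescan intensity matrix (one ablation line per row) or the
#'   `linescan` list from [simulate_laicpms_experiment()].
#' @param curve a valid [calibration_curve][fit_calibration].
#' @return an object of class `element_map`: `values` (ug/g), `sub_lod`
#'   flags, element and spot geometry.
#' @export
quantify_linescans <- function(linescan, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!curve$valid) stop("calibration curve is invalid (nonpositive slope)")
  meta <- list(element = curve$element, spot_size_um = 15,
               scan_speed_um_per_s = 30)
  if (is.list(linescan) && !is.null(linescan$intensity)) {
    meta$element <- linescan$element %||% meta$element
    meta$spot_size_um <- linescan$spot_size_um %||% meta$spot_size_um
    meta$scan_speed_um_per_s <- linescan$scan_speed_um_per_s %||%
      meta$scan_speed_um_per_s
    meta$row_voxel <- linescan$row_voxel
    meta$col_voxel <- linescan$col_voxel
    linescan <- linescan$intensity
  }
  if (!is.matrix(linescan)) stop("line-scan rows must have equal length")
  conc <- (linescan - curve$intercept) / curve$slope
  structure(c(list(values = conc, sub_lod = conc < curve$lod), meta),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("<element_map> %s: %d lines x %d spots at %g um, %.1f%% sub-LOD\n",
              x$element, nrow(x$values), ncol(x$values), x$spot_size_um,
              100 * mean(x$sub_lod)))
  invisible(x)
}

#' Mean elemental concentration of a section
#'
#' @param map an [element_map][quantify_linescans].
#' @param mask optional [roi_mask()] on the line-scan grid; `NULL` averages
#'   all spots.
#' @return mean concentration in ug/g.
#' @export
section_mean <- function(map, mask = NULL) {
  stopifnot(inherits(map, "element_map"))
  if (is.null(mask)) return(mean(map$values))
  check_mask(mask, dim(map$values))
  mean(map$values[mask$grid])
}

#' Summarize triplicate section means
#'
#' @param section_means exactly 3 per-section mean concentrations (ug/g).
#' @return an object of class `triplicate_summary`: the three section
#'   means, their arithmetic mean and sample (n-1) standard deviation.
#' @export
triplicate_summary <- function(section_means) {
  if (length(section_means) != 3) stop("exactly 3 section means required")
  structure(list(section_means = as.numeric(section_means),
                 mean = mean(section_means),
                 std = stats::sd(section_means)),
            class = "triplicate_summary")
}

#' @export
print.triplicate_summary <- function(x, ...) {
  cat(sprintf("<triplicate_summary> %.4g +/- %.4g ug/g\n", x$mean, x$std))
  invisible(x)
}
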