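# First-order histogram features of parameter maps within the tumor ROI.

#' Histogram feature configuration
#'
#' @param n_bins number of equal-width bins for the entropy histogram
#'   (>= 2; spans the sample min-max).
#' @param kurtosis_convention `"excess"` (bias-corrected excess kurtosis,
#'   normal -> 0) or `"pearson"` (normal -> 3).
#' @return an object of class `histogram_config`.
#' @export
histogram_config <- function(n_bins = 64,
                             kurtosis_convention = c("excess", "pearson")) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(list(n_bins = as.integer(n_bins),
                 kurtosis_convention = match.arg(kurtosis_convention)),
            class = "histogram_config")
}

#' Extract the ROI value sample from a parameter map
#'
#' Returns the masked, valid voxel values in deterministic row-major order.
#'
#' @param map a [parameter_map()].
#' @param mask an [roi_mask()] of the same dimensions.
#' @return numeric vector of values.
#' @export
extract_roi_sample <- function(map, mask) {
  stopifnot(inherits(map, "parameter_map"))
  check_mask(mask, dim(map$values))
  sel <- mask$grid & map$valid
  if (!any(sel)) stop("no valid voxels inside the ROI")
  t(map$values)[t(sel)]
}

#' Linear-interpolation percentile
#'
#' The quantile at rank `h = (n - 1) p / 100 + 1`, linearly interpolated
#' between order statistics (the convention of most analysis tools;
#' `stats::quantile` type 7).
#'
#' @param sample nonempty numeric vector.
#' @param p percentile in `[0, 100]`.
#' @return the percentile value.
#' @export
percentile <- function(sample, p) {
  if (!length(sample)) stop("sample must be nonempty")
  if (p < 0 || p > 100) stop("p must be in [0, 100]")
  unname(stats::quantile(sample, p / 100, type = 7, names = FALSE))
}

#' Shannon entropy of the binned value distribution
#'
#' Histograms the sample into `n_bins` equal-width bins spanning its
#' min-max range and returns `-sum f_i log2 f_i` over occupied bins.
#' A constant sample occupies a single bin and has zero entropy.
#'
#' @param sample nonempty numeric vector.
#' @param config a [histogram_config()].
#' @return entropy in bits, in `[0, log2(n_bins)]`.
#' @export
shannon_entropy <- function(sample, config = histogram_config()) {
  if (!length(sample)) stop("sample must be nonempty")
  lo <- min(sample); hi <- max(sample)
  if (hi <= lo) return(0)
  breaks <- seq(lo, hi, length.out = config$n_bins + 1L)
  bin <- findInterval(sample, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  f <- tabulate(bin, nbins = config$n_bins) / length(sample)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' First-order feature set of an ROI sample
#'
#' Mean, bias-corrected sample skewness (adjusted Fisher-Pearson G1),
#' bias-corrected kurtosis (G2, excess by default), range, 90th percentile,
#' interquartile range and binned Shannon entropy. Moment features need
#' `n >= 4` and nonzero variance; otherwise they are `NA`.
#'
#' @param sample numeric vector of ROI values.
#' @param config a [histogram_config()].
#' @return an object of class `feature_set`.
#' @export
compute_feature_set <- function(sample, config = histogram_config()) {
  if (!length(sample)) stop("sample must be nonempty")
  n <- length(sample)
  sk <- ku <- NA_real_
  if (n >= 4 && stats::sd(sample) > 0) {
    sk <- e1071::skewness(sample, type = 2)
    ku <- e1071::kurtosis(sample, type = 2)
    if (config$kurtosis_convention == "pearson") ku <- ku + 3
  }
  structure(list(
    mean = mean(sample),
    skewness = sk,
    kurtosis = ku,
    range = max(sample) - min(sample),
    p90 = percentile(sample, 90),
    iqr = percentile(sample, 75) - percentile(sample, 25),
    entropy_bits = shannon_entropy(sample, config),
    n_voxels = n
  ), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(paste0("<feature_set> n %d: mean %.4g, skew %.3g, kurt %.3g, ",
                     "range %.4g, p90 %.4g, IQR %.4g, entropy %.3g bits\n"),
              x$n_voxels, x$mean, x$skewness, x$kurtosis, x$range, x$p90,
              x$iqr, x$entropy_bits))
  invisible(x)
}
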