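# Normality-gated group statistics, Pearson correlation and PCA over the
# fixed ten-variable feature table.

#' The ten feature-table variables entering PCA
#'
#' @return character vector of the fixed column names.
#' @export
pca_feature_columns <- function() {
  c("ADC_mean", "ADC_kurtosis", "ADC_range", "ADC_p90", "delta_T1",
    "Ktrans", "AUC", "slope_max", "T1", "T2")
}

#' Normality gate for test selection
#'
#' Runs the Shapiro-Wilk test on every group; the comparison is declared
#' nonparametric as soon as any group rejects normality at `alpha`.
#'
#' @param groups list of numeric vectors, each of length >= 3.
#' @param alpha significance level of the normality test.
#' @return list with `choice` (`"parametric"` or `"nonparametric"`),
#'   `p_values` (per group) and `alpha`.
#' @export
shapiro_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (any(vapply(groups, length, 0L) < 3))
    stop("Shapiro-Wilk requires n >= 3 in every group")
  p <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, 0)
  list(choice = if (any(p < alpha)) "nonparametric" else "parametric",
       p_values = p, alpha = alpha)
}

test_result <- function(test_name, statistic, p_value, gate_trace = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), gate_trace = gate_trace),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p %.4g\n",
              x$test_name, x$statistic, x$p_value))
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Two-sided unpaired Welch t-test when both groups pass the Shapiro-Wilk
#' gate, otherwise a two-sided Mann-Whitney U test (exact when both
#' `n <= 8` and the data are tie-free, normal approximation with tie and
#' continuity correction otherwise).
#'
#' @param a,b numeric vectors (n >= 2; the gate itself needs n >= 3).
#' @param gate optional pre-computed [shapiro_gate()] result; computed from
#'   `a` and `b` when `NULL`.
#' @param alpha gate significance level.
#' @return a `test_result` with the gate decisions in `gate_trace`.
#' @export
compare_two_groups <- function(a, b, gate = NULL, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) stop("both groups need n >= 2")
  if (is.null(gate)) gate <- shapiro_gate(list(a, b), alpha)
  if (gate$choice == "parametric") {
    ht <- stats::t.test(a, b)
    test_result("t_test", ht$statistic, ht$p.value, gate)
  } else {
    exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    test_result("mann_whitney_u", ht$statistic, ht$p.value, gate)
  }
}

#' Normality-gated comparison across time points
#'
#' One-way ANOVA when all groups pass the Shapiro-Wilk gate, otherwise the
#' Kruskal-Wallis rank-sum test.
#'
#' @param groups list of numeric vectors (one per day).
#' @param gate optional pre-computed gate.
#' @param alpha gate significance level.
#' @return a `test_result`.
#' @export
compare_over_time <- function(groups, gate = NULL, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 0L) < 2)) stop("every group needs n >= 2")
  if (is.null(gate)) gate <- shapiro_gate(groups, alpha)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (gate$choice == "parametric") {
    fit <- stats::aov(values ~ fac)
    s <- summary(fit)[[1]]
    test_result("anova", s$`F value`[1], s$`Pr(>F)`[1], gate)
  } else {
    ht <- stats::kruskal.test(values, fac)
    test_result("kruskal_wallis", ht$statistic, ht$p.value, gate)
  }
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), nonzero variance.
#' @return a `test_result` with the correlation coefficient as statistic.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result("pearson", ht$estimate, ht$p.value)
}

#' Z-score the feature columns of a table
#'
#' Standardizes every feature column to mean 0, sd 1 (n-1 denominator);
#' identifier columns (`tumor_id`, `phenotype`, `day`) pass through.
#'
#' @param table data.frame containing the [pca_feature_columns()] (or any
#'   all-numeric data.frame).
#' @return the table with standardized feature columns.
#' @export
zscore_columns <- function(table) {
  stopifnot(is.data.frame(table))
  cols <- intersect(pca_feature_columns(), names(table))
  if (!length(cols)) cols <- names(table)[vapply(table, is.numeric, TRUE)]
  for (cl in cols) {
    v <- table[[cl]]
    if (!is.numeric(v)) stop("feature columns must be numeric")
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop(sprintf("column '%s' is constant", cl))
    table[[cl]] <- (v - mean(v)) / s
  }
  table
}

#' Principal component analysis of the feature table
#'
#' Singular-value decomposition of the centered (z-scored) feature matrix.
#' The per-component explained-variance ratio is `lambda_i / sum(lambda)`;
#' with all ten components retained on a full-rank table the ratios sum to
#' one. The sign of each component is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param table data.frame carrying the [pca_feature_columns()] (already
#'   z-scored, see [zscore_columns()]).
#' @param n_components number of components to keep
#'   (`<= min(n_rows - 1, n_vars)`).
#' @return an object of class `pca_result`: `loadings` (vars x k),
#'   `scores` (n x k), `variance_ratio` (k), `center`.
#' @export
run_pca <- function(table, n_components = 10) {
  stopifnot(is.data.frame(table))
  cols <- intersect(pca_feature_columns(), names(table))
  if (!length(cols)) cols <- names(table)[vapply(table, is.numeric, TRUE)]
  x <- as.matrix(table[, cols, drop = FALSE])
  if (anyNA(x)) stop("feature table has missing values")
  if (nrow(x) < 2) stop("PCA needs at least 2 rows")
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax)
    stop(sprintf("n_components must be <= min(n_rows - 1, %d) = %d",
                 ncol(x), kmax))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  ratio <- lambda / sum(lambda)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(load[, i]))
    if (load[j, i] < 0) { load[, i] <- -load[, i]; scores[, i] <- -scores[, i] }
  }
  structure(list(loadings = load, scores = scores,
                 variance_ratio = ratio[seq_len(k)], center = pc$center,
                 all_variance = lambda),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained variance: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_ratio), collapse = " ")))
  invisible(x)
}

#' PC1-threshold phenotype classification accuracy
#'
#' Classifies samples by thresholding their first principal component score
#' at the midpoint between the two group mean scores, and returns the
#' accuracy of the better orientation.
#'
#' @param scores_pc1 numeric vector of PC1 scores.
#' @param labels two-level factor or character vector.
#' @return classification accuracy in `[0, 1]`.
#' @export
pc1_threshold_accuracy <- function(scores_pc1, labels) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2, length(scores_pc1) == length(labels))
  mu <- tapply(scores_pc1, labels, mean)
  thr <- mean(mu)
  pred <- levels(labels)[(scores_pc1 > thr) + 1L]
  acc <- mean(pred == as.character(labels))
  max(acc, 1 - acc)
}
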