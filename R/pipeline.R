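# End-to-end orchestration: per-tumor processing into a feature-table row,
# cohort-level study run, volumetry.

#' Study configuration
#'
#' Collects every tunable of the pipeline: phantom generation, acquisition
#' axes and noise, fit settings, DCE conversion/AIF, LA-ICP-MS calibration
#' and the statistics block. All values are plain R lists so a
#' configuration round-trips through YAML (see [write_study_config()]).
#'
#' @param n_per_group tumors per phenotype per day.
#' @param days measurement days.
#' @param grid_shape phantom grid.
#' @param seed master seed; every stream below derives from it.
#' @param noise_sd list of per-series additive noise levels (a.u.): `t1`,
#'   `t2`, `dwi`, `dce`.
#' @param tr_ms,te_ms,b_values acquisition axes.
#' @param timing,aif,conversion DCE settings ([dce_timing()],
#'   [aif_model()], [dce_conversion()]).
#' @param fit a [fit_config()].
#' @param histogram a [histogram_config()].
#' @param tofts a [tofts_fit_config()].
#' @param laicpms list: `standard_levels`, `sensitivity`, `blank_sd`,
#'   `heteroscedasticity`, `intercept`, `n_sections`, `enabled`.
#' @param alpha significance level for the gated statistics.
#' @param smooth_window frames for the slope_max moving average.
#' @param param_ranges phantom truth ranges ([default_param_ranges()]).
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_per_group = 8, days = c(3, 6, 9),
                         grid_shape = c(32, 32), seed = 42,
                         noise_sd = list(t1 = 5, t2 = 5, dwi = 5, dce = 0.5),
                         tr_ms = default_tr_ms(), te_ms = default_te_ms(),
                         b_values = default_b_values(),
                         timing = dce_timing(), aif = aif_model(),
                         conversion = dce_conversion("relaxivity"),
                         fit = fit_config(), histogram = histogram_config(),
                         tofts = tofts_fit_config(),
                         laicpms = list(standard_levels = seq(0, 600, 100),
                                        sensitivity = 10, blank_sd = 2,
                                        heteroscedasticity = 0.005,
                                        intercept = 50, n_sections = 3,
                                        enabled = TRUE),
                         alpha = 0.05, smooth_window = 3,
                         param_ranges = default_param_ranges()) {
  structure(as.list(environment()), class = "study_config")
}

#' Tumor volume from stacked ROI masks
#'
#' Voxel count times voxel volume, summed over slices.
#'
#' @param mask_stack an [roi_mask()] or list of them (one per slice).
#' @param pixel_spacing in-plane spacing in mm (length 2).
#' @param slice_thickness slice thickness in mm.
#' @return volume in mm^3.
#' @export
compute_tumor_volume <- function(mask_stack, pixel_spacing = c(0.28, 0.28),
                                 slice_thickness = 1) {
  if (inherits(mask_stack, "roi_mask")) mask_stack <- list(mask_stack)
  if (!length(mask_stack)) stop("need at least one slice")
  vox <- prod(pixel_spacing) * slice_thickness
  sum(vapply(mask_stack, n_voxels, 0L)) * vox
}

#' Forward-simulate the full acquisition bundle for one tumor
#'
#' Produces everything [process_tumor()] consumes: variable-TR T1 series
#' before and after contrast (post-contrast T1 shortened by the retained
#' Gd), the multi-echo T2 series, the multi-b DWI series, the dynamic DCE
#' series, and (optionally) LA-ICP-MS standards plus triplicate line-scan
#' sections.
#'
#' @param truth a `phantom_truth`.
#' @param config a [study_config()].
#' @return named list of series keyed by stage, plus `truth`.
#' @export
simulate_acquisitions <- function(truth, config = study_config()) {
  s <- truth$seed
  nz <- config$noise_sd
  t1_post_vals <- post_contrast_t1(truth, r1 = config$conversion$r1)
  bundle <- list(
    truth = truth,
    t1_pre = simulate_t1_series(truth, config$tr_ms, nz$t1, seed = s),
    t1_post = simulate_t1_series(truth, config$tr_ms, nz$t1,
                                 seed = derive_seed(s, "post"),
                                 t1_ms = t1_post_vals),
    t2 = simulate_t2_series(truth, config$te_ms, nz$t2, seed = s),
    dwi = simulate_dwi_series(truth, config$b_values, nz$dwi, seed = s),
    dce = simulate_dce_series(truth, config$timing, config$aif,
                              config$conversion, nz$dce, seed = s)
  )
  if (isTRUE(config$laicpms$enabled)) {
    la <- config$laicpms
    bundle$laicpms <- lapply(seq_len(la$n_sections), function(k)
      simulate_laicpms_experiment(
        truth, la$standard_levels, la$sensitivity, la$blank_sd,
        la$heteroscedasticity, la$intercept,
        seed = derive_seed(s, paste0("section", k))))
  }
  bundle
}

require_stage <- function(bundle, name, stage) {
  if (is.null(bundle[[name]]))
    stop(sprintf("missing series for the %s stage ('%s')", stage, name))
  bundle[[name]]
}

#' Process one tumor into a feature-table row
#'
#' Runs the full per-tumor chain: T1 mapping before and after contrast,
#' delta-T1, T2 and ADC mapping, histogram features of the ADC / T1 / T2 /
#' post-contrast T1 maps, ROI-level DCE analysis (relative-enhancement
#' semi-quantitative metrics; extended Tofts Ktrans from the
#' relaxivity-converted ROI curve), volumetry, and LA-ICP-MS quantification
#' when line scans are present. Emits the ten fixed feature-table variables
#' plus the secondary histogram features.
#'
#' @param bundle a `phantom_truth` (acquisitions are simulated on the fly)
#'   or the list from [simulate_acquisitions()].
#' @param config a [study_config()].
#' @return an object of class `tumor_record`.
#' @export
process_tumor <- function(bundle, config = study_config()) {
  if (inherits(bundle, "phantom_truth"))
    bundle <- simulate_acquisitions(bundle, config)
  truth <- bundle$truth
  mask <- truth$tumor_mask
  hc <- config$histogram

  t1_pre <- fit_t1_map(require_stage(bundle, "t1_pre", "pre-contrast T1"),
                       mask, config$fit)
  t1_post <- fit_t1_map(require_stage(bundle, "t1_post", "post-contrast T1"),
                        mask, config$fit)
  t2 <- fit_t2_map(require_stage(bundle, "t2", "T2 mapping"), mask, config$fit)
  adc <- fit_adc_map(require_stage(bundle, "dwi", "diffusion"), mask, config$fit)
  dt1 <- delta_t1_map(t1_pre, t1_post)

  adc_fs <- compute_feature_set(extract_roi_sample(adc, mask), hc)
  t1_fs <- compute_feature_set(extract_roi_sample(t1_pre, mask), hc)
  t2_fs <- compute_feature_set(extract_roi_sample(t2, mask), hc)
  t1p_fs <- compute_feature_set(extract_roi_sample(t1_post, mask), hc)
  dt1_sample <- extract_roi_sample(dt1, mask)

  dce <- require_stage(bundle, "dce", "DCE")
  sig <- roi_curve(dce, mask, config$timing)
  enh <- signal_to_concentration(sig$values, config$timing,
                                 conversion = dce_conversion("relative"))
  sq <- semiquant_metrics(
    concentration_curve(enh$times_s, enh$values[, 1], "enhancement"),
    config$timing, config$smooth_window)
  t1_0_roi <- mean(extract_roi_sample(t1_pre, mask))
  conc <- signal_to_concentration(sig$values, config$timing,
                                  t1_0_ms = t1_0_roi,
                                  conversion = config$conversion)
  cp <- population_aif(config$timing, config$aif)
  pk <- fit_extended_tofts(conc$values[, 1], cp$values,
                           times_s = conc$times_s, config$tofts)

  gd <- NULL
  if (!is.null(bundle$laicpms)) {
    sections <- vapply(bundle$laicpms, function(la) {
      curve <- fit_calibration(la$standards)
      section_mean(quantify_linescans(la$linescan, curve))
    }, 0)
    gd <- triplicate_summary(sections)
  }

  features <- c(
    ADC_mean = adc_fs$mean, ADC_kurtosis = adc_fs$kurtosis,
    ADC_range = adc_fs$range, ADC_p90 = adc_fs$p90,
    delta_T1 = mean(dt1_sample), Ktrans = pk$ktrans_per_min,
    AUC = sq$auc, slope_max = sq$slope_max,
    T1 = t1_fs$mean, T2 = t2_fs$mean)

  structure(list(
    tumor_id = sprintf("%s_d%d_s%d",
                       substr(truth$phenotype, 1, 3), truth$day, truth$seed),
    phenotype = truth$phenotype, day = truth$day,
    volume_mm3 = compute_tumor_volume(mask, truth$pixel_spacing,
                                      truth$slice_thickness),
    features = features,
    feature_sets = list(ADC = adc_fs, T1 = t1_fs, T2 = t2_fs,
                        T1_post = t1p_fs),
    extra = list(T1_entropy = t1_fs$entropy_bits, T2_IQR = t2_fs$iqr,
                 T1_post_entropy = t1p_fs$entropy_bits,
                 T1_post_skewness = t1p_fs$skewness,
                 peak_enhancement = sq$peak_enhancement),
    pk = pk, gd = gd,
    maps = list(T1 = t1_pre, T1_post = t1_post, T2 = t2, ADC = adc,
                deltaT1 = dt1)
  ), class = "tumor_record")
}

#' @export
print.tumor_record <- function(x, ...) {
  cat(sprintf("<tumor_record> %s (%s, day %d): volume %.1f mm^3, Ktrans %.3g /min\n",
              x$tumor_id, x$phenotype, x$day, x$volume_mm3,
              x$features[["Ktrans"]]))
  invisible(x)
}

record_row <- function(rec) {
  cbind(data.frame(tumor_id = rec$tumor_id, phenotype = rec$phenotype,
                   day = rec$day, volume_mm3 = rec$volume_mm3,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(rec$features)),
        data.frame(gd_ug_per_g = if (is.null(rec$gd)) NA_real_ else rec$gd$mean))
}

#' Run the full synthetic study
#'
#' Generates the phantom cohort, processes every tumor, assembles the
#' feature table, runs the gated group comparisons (phenotype contrast at
#' each day; change over days within each phenotype) for every feature,
#' correlates delta-T1 with the LA-ICP-MS Gd section means, and performs
#' the per-day (and pooled) PCA with PC1-threshold phenotype
#' classification. Optionally writes all tables to `out_dir`.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param progress print per-tumor progress.
#' @return an object of class `study_report`: `feature_table`,
#'   `comparisons`, `pca` (per day + pooled), `pc1_accuracy`,
#'   `correlation`, `manifest`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- make_cohort(config$n_per_group, config$days, config$seed,
                        grid_shape = config$grid_shape,
                        param_ranges = config$param_ranges)
  records <- lapply(seq_along(cohort$phantoms), function(i) {
    if (progress) message("processing ", cohort$manifest$tumor_id[i])
    process_tumor(cohort$phantoms[[i]], config)
  })
  ft <- do.call(rbind, lapply(records, record_row))
  ft$tumor_id <- cohort$manifest$tumor_id

  vars <- pca_feature_columns()
  comparisons <- list()
  for (v in vars) {
    for (d in config$days) {
      a <- ft[[v]][ft$phenotype == PHENOTYPES[1] & ft$day == d]
      b <- ft[[v]][ft$phenotype == PHENOTYPES[2] & ft$day == d]
      res <- compare_two_groups(a, b, alpha = config$alpha)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        variable = v, contrast = "phenotype", day = d,
        test = res$test_name, statistic = res$statistic,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
    for (ph in PHENOTYPES) {
      gl <- lapply(config$days, function(d)
        ft[[v]][ft$phenotype == ph & ft$day == d])
      res <- compare_over_time(gl, alpha = config$alpha)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        variable = v, contrast = paste0("time_", ph), day = NA,
        test = res$test_name, statistic = res$statistic,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, comparisons)

  correlation <- NULL
  if (!anyNA(ft$gd_ug_per_g))
    correlation <- pearson_correlation(ft$delta_T1, ft$gd_ug_per_g)

  pca <- list(); acc <- c()
  for (d in config$days) {
    sub <- ft[ft$day == d, ]
    z <- zscore_columns(sub)
    k <- min(nrow(sub) - 1L, length(vars))
    p <- run_pca(z, n_components = k)
    pca[[paste0("day", d)]] <- p
    acc[paste0("day", d)] <- pc1_threshold_accuracy(p$scores[, 1],
                                                    sub$phenotype)
  }
  pca$pooled <- run_pca(zscore_columns(ft),
                        n_components = min(nrow(ft) - 1L, length(vars)))

  report <- structure(list(feature_table = ft, comparisons = comparisons,
                           pca = pca, pc1_accuracy = acc,
                           correlation = correlation,
                           manifest = cohort$manifest, config = config),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d tumors, %d comparisons\n",
              nrow(x$feature_table), nrow(x$comparisons)))
  cat("  PC1 phenotype accuracy:",
      paste(sprintf("%s %.2f", names(x$pc1_accuracy), x$pc1_accuracy),
            collapse = ", "), "\n")
  if (!is.null(x$correlation))
    cat(sprintf("  deltaT1 ~ Gd: r = %.4f, p = %.4g\n",
                x$correlation$statistic, x$correlation$p_value))
  invisible(x)
}

#' Group-mean directional contrasts between the two phenotypes
#'
#' Computes, from a feature table, whether each constructed contrast holds
#' in the phenotype group means (pooled over days): higher Ktrans,
#' delta-T1, ADC kurtosis/range/p90 and T1 in the heterogeneous phenotype;
#' higher AUC and slope_max in the homogeneous phenotype.
#'
#' @param feature_table the `feature_table` of a [run_study()] report.
#' @return named logical vector, one entry per contrast.
#' @export
directional_contrasts <- function(feature_table) {
  het <- feature_table$phenotype == PHENOTYPES[1]
  m <- function(v, grp) mean(feature_table[[v]][grp])
  higher_het <- c("Ktrans", "delta_T1", "ADC_kurtosis", "ADC_range",
                  "ADC_p90", "T1")
  higher_hom <- c("AUC", "slope_max")
  out <- c(
    vapply(higher_het, function(v) m(v, het) > m(v, !het), TRUE),
    vapply(higher_hom, function(v) m(v, !het) > m(v, het), TRUE))
  names(out) <- c(paste0(higher_het, "_higher_het"),
                  paste0(higher_hom, "_higher_hom"))
  out
}
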