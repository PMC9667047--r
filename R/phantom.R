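# Digital tumor phantom: ground-truth maps and forward-simulated acquisitions.

PHENOTYPES <- c("heterogeneous_metastatic", "homogeneous_nonmetastatic")
PHANTOM_DAYS <- c(3, 6, 9)

#' Default acquisition axes
#'
#' The repetition times, echo times and diffusion weightings used as
#' defaults by all simulators and fits: eight TRs from 123 to 7500 ms,
#' five TEs from 10 to 90 ms, and twelve b-values from 20 to 2200 s/mm^2,
#' matching a combined T1/T2 RARE mapping protocol and a multi-b DW-EPI
#' protocol on a 9.4 T small-animal system.
#'
#' @return numeric vector of axis values (ascending).
#' @export
default_tr_ms <- function() c(123, 311, 400, 800, 1500, 3000, 5000, 7500)

#' @rdname default_tr_ms
#' @export
default_te_ms <- function() c(10, 30, 50, 70, 90)

#' @rdname default_tr_ms
#' @export
default_b_values <- function()
  c(20, 100, 200, 300, 400, 600, 800, 1000, 1200, 1500, 1800, 2200)

#' Default ground-truth parameter ranges for the phantom
#'
#' Tissue-class intervals from which per-tumor base values are drawn.
#' The heterogeneous (metastatic-like) phenotype has a viable rim and a
#' necrotic core with longer T1/T2, elevated ADC and near-zero Ktrans;
#' the homogeneous (non-metastatic-like) phenotype is uniform, densely
#' cellular tissue with intact perfusion (higher ve/vp, lower Ktrans).
#' Units: T1/T2 ms, ADC mm^2/s, Ktrans 1/min, ve/vp fractions, s0 a.u.,
#' Gd ug/g tissue.
#'
#' @return nested list of `c(lo, hi)` intervals per tissue class.
#' @export
default_param_ranges <- function() {
  list(
    het_rim = list(t1 = c(1800, 2200), t2 = c(40, 55), adc = c(0.6e-3, 0.9e-3),
                   ktrans = c(0.20, 0.50), ve = c(0.20, 0.35),
                   vp = c(0.01, 0.03), gd = c(30, 60)),
    het_core = list(t1 = c(2400, 2800), t2 = c(55, 80), adc = c(1.5e-3, 2.5e-3),
                    ktrans = c(0.0, 0.02), ve = c(0.02, 0.08),
                    vp = c(0, 0.005), gd = c(10, 25)),
    hom = list(t1 = c(1500, 1900), t2 = c(30, 45), adc = c(0.9e-3, 1.2e-3),
               ktrans = c(0.05, 0.15), ve = c(0.35, 0.50),
               vp = c(0.05, 0.10), gd = c(5, 15)),
    s0 = c(450, 550),
    # fraction of viable-rim voxels carrying sub-resolution edema/necrosis
    # foci, and the mean of the exponential ADC elevation they add: gives
    # the heterogeneous phenotype a heavy right ADC tail at every time point
    speckle_fraction = 0.25,
    speckle_tail_adc = 0.6e-3,
    # relative amplitude of the smooth within-class spatial variation
    field_amplitude = 0.05,
    # necrotic-core radius as a fraction of the tumor radius, by day
    core_radius_fraction = c(`3` = 0.15, `6` = 0.25, `9` = 0.35),
    # per-day Gd retention decline (both phenotypes accumulate less later)
    gd_day_factor = c(`3` = 1.0, `6` = 0.85, `9` = 0.70)
  )
}

rand_in <- function(range) stats::runif(1, range[1], range[2])

#' Generate a synthetic tumor with known ground truth
#'
#' Builds an elliptical tumor on a 2D grid with per-voxel ground-truth maps
#' of T1, T2, ADC, the extended Tofts parameters (Ktrans, ve, vp), proton
#' density scaling s0 and retained gadolinium concentration. The
#' heterogeneous phenotype carries a necrotic core whose radius grows with
#' day plus scattered high-ADC foci in the rim; the homogeneous phenotype is
#' spatially uniform up to a low-amplitude smooth field. Identical seed and
#' arguments give a bit-identical phantom.
#'
#' @param phenotype `"heterogeneous_metastatic"` or
#'   `"homogeneous_nonmetastatic"` (prefix-matched).
#' @param day measurement day, one of 3, 6, 9.
#' @param grid_shape 2 integers >= 16.
#' @param seed integer master seed for this tumor.
#' @param param_ranges see [default_param_ranges()].
#' @param pixel_spacing,slice_thickness voxel geometry in mm.
#' @return an object of class `phantom_truth`: the two masks plus one
#'   [parameter_map()] per ground-truth quantity.
#' @export
make_phantom <- function(phenotype, day, grid_shape = c(32, 32), seed = 1,
                         param_ranges = default_param_ranges(),
                         pixel_spacing = c(0.28, 0.28), slice_thickness = 1) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  if (!(length(day) == 1L && day %in% PHANTOM_DAYS))
    stop("unknown day: must be one of 3, 6, 9")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 16L))
    stop("grid_shape must be at least 16 x 16")
  pr <- param_ranges
  nr <- grid_shape[1]; nc <- grid_shape[2]
  het <- phenotype == "heterogeneous_metastatic"

  set.seed(derive_seed(seed, "phantom-geometry"))
  # tumor semi-axes in voxels; the metastatic-like phenotype grows faster
  f <- if (het) 0.20 + 0.025 * day else 0.20 + 0.012 * day
  half <- min(nr, nc) / 2
  a <- f * half
  b <- 0.85 * a
  cy <- nr / 2 + stats::runif(1, -1, 1)
  cx <- nc / 2 + stats::runif(1, -1, 1)
  theta <- stats::runif(1, 0, pi)

  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  u <- (row_idx - cy) * cos(theta) + (col_idx - cx) * sin(theta)
  v <- -(row_idx - cy) * sin(theta) + (col_idx - cx) * cos(theta)
  r2 <- (u / a)^2 + (v / b)^2
  tumor <- r2 <= 1
  core_frac <- if (het) unname(pr$core_radius_fraction[as.character(day)]) else 0
  core <- r2 <= core_frac^2
  core[!tumor] <- FALSE

  set.seed(derive_seed(seed, "phantom-values"))
  amp <- pr$field_amplitude
  draw_map <- function(key, background) {
    rim_rng <- if (het) pr$het_rim[[key]] else pr$hom[[key]]
    base_rim <- rand_in(rim_rng)
    base_core <- if (het) rand_in(pr$het_core[[key]]) else base_rim
    fld <- smooth_field(nr, nc)
    m <- matrix(background, nr, nc)
    m[tumor] <- base_rim * (1 + amp * fld[tumor])
    if (het && any(core)) m[core] <- base_core * (1 + amp * fld[core])
    m
  }

  t1 <- draw_map("t1", background = 1200)
  t2 <- draw_map("t2", background = 25)
  adc <- draw_map("adc", background = 1.0e-3)
  ktrans <- pmax(draw_map("ktrans", background = 0.02), 0)
  ve <- draw_map("ve", background = 0.10)
  vp <- pmax(draw_map("vp", background = 0.01), 0)
  gd <- pmax(draw_map("gd", background = 1), 0) *
    unname(pr$gd_day_factor[as.character(day)])
  s0 <- matrix(rand_in(pr$s0), nr, nc) * (1 + amp * smooth_field(nr, nc))

  if (het) {
    # sub-resolution necrotic/edematous foci scattered through the rim:
    # an exponential ADC elevation without joining the coherent core mask
    rim_idx <- which(tumor & !core)
    n_spk <- round(pr$speckle_fraction * length(rim_idx))
    if (n_spk > 0) {
      spk <- sample(rim_idx, n_spk)
      adc[spk] <- adc[spk] + stats::rexp(n_spk, 1 / pr$speckle_tail_adc)
    }
  }

  # enforce physical invariants
  adc <- pmin(pmax(adc, 1e-4), 4e-3)
  scale_ev <- pmax(ve + vp, 1)
  ve <- ve / scale_ev; vp <- vp / scale_ev

  all_valid <- matrix(TRUE, nr, nc)
  pm <- function(vals, name, units) parameter_map(vals, name, units, all_valid)
  structure(list(
    phenotype = phenotype, day = day, seed = seed,
    tumor_mask = roi_mask(tumor, "tumor"),
    necrosis_mask = roi_mask(core, "necrosis"),
    t1_ms = pm(t1, "T1", "ms"),
    t2_ms = pm(t2, "T2", "ms"),
    adc_mm2_per_s = pm(adc, "ADC", "mm^2/s"),
    ktrans_per_min = pm(ktrans, "Ktrans", "1/min"),
    ve_frac = pm(ve, "ve", "fraction"),
    vp_frac = pm(vp, "vp", "fraction"),
    s0_au = pm(s0, "s0", "a.u."),
    gd_ug_per_g = pm(gd, "Gd", "ug/g"),
    pixel_spacing = pixel_spacing, slice_thickness = slice_thickness
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s, day %d, %d x %d, seed %d\n",
              x$phenotype, x$day, nrow(x$tumor_mask$grid),
              ncol(x$tumor_mask$grid), x$seed))
  cat(sprintf("  tumor %d voxels, necrotic fraction %.3f\n",
              n_voxels(x$tumor_mask), necrotic_fraction(x)))
  invisible(x)
}

#' Necrotic area fraction of a phantom
#' @param truth a `phantom_truth`.
#' @return necrotic core voxels / tumor voxels.
#' @export
necrotic_fraction <- function(truth) {
  n_voxels(truth$necrosis_mask) / n_voxels(truth$tumor_mask)
}

# Gd molar mass, g/mol; bridges ug/g tissue (density ~1 g/mL) to mM.
GD_MOLAR_MASS <- 157.25

#' Post-contrast T1 implied by retained gadolinium
#'
#' Converts the phantom's retained Gd concentration (ug/g, tissue density
#' taken as 1 g/mL) to mM and shortens T1 via R1_post = R1_pre + r1 * C.
#'
#' @param truth a `phantom_truth`.
#' @param r1 longitudinal relaxivity in L mmol^-1 s^-1.
#' @return matrix of post-contrast T1 values (ms).
#' @export
post_contrast_t1 <- function(truth, r1 = 6.0) {
  c_mM <- truth$gd_ug_per_g$values / GD_MOLAR_MASS
  r1_pre <- 1000 / truth$t1_ms$values       # 1/s
  1000 / (r1_pre + r1 * c_mM)
}

add_noise <- function(signal, noise_sd, rician = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(signal)
  if (rician) {
    sqrt((signal + stats::rnorm(length(signal), 0, noise_sd))^2 +
           stats::rnorm(length(signal), 0, noise_sd)^2)
  } else {
    pmax(signal + stats::rnorm(length(signal), 0, noise_sd), 0)
  }
}

series_from_maps <- function(truth, axis_kind, axis_values, signal_fun,
                             noise_sd, seed, stream, rician = FALSE) {
  nr <- nrow(truth$tumor_mask$grid); nc <- ncol(truth$tumor_mask$grid)
  nf <- length(axis_values)
  frames <- array(0, c(nr, nc, nf))
  for (i in seq_len(nf)) frames[, , i] <- signal_fun(axis_values[i])
  set.seed(derive_seed(seed, stream))
  frames <- array(add_noise(frames, noise_sd, rician), dim(frames))
  new_image_series(frames, axis_kind, axis_values,
                   pixel_spacing = truth$pixel_spacing,
                   slice_thickness = truth$slice_thickness)
}

#' Forward-simulate a variable-TR T1 mapping series
#'
#' Saturation-recovery signal `SI(TR) = s0 * (1 - exp(-TR/T1))` per voxel
#' (zero offset), with optional additive Gaussian (or Rician) noise.
#'
#' @param truth a `phantom_truth`.
#' @param tr_list repetition times in ms (ascending).
#' @param noise_sd additive noise standard deviation (a.u.).
#' @param seed integer seed for the noise stream.
#' @param rician simulate magnitude (Rician) noise instead of additive
#'   Gaussian.
#' @param t1_ms optional T1 matrix overriding the truth map (used for
#'   post-contrast series, see [post_contrast_t1()]).
#' @return an [image_series()] along `repetition_time`.
#' @export
simulate_t1_series <- function(truth, tr_list = default_tr_ms(), noise_sd = 0,
                               seed = 1, rician = FALSE, t1_ms = NULL) {
  if (any(tr_list <= 0)) stop("tr_list must be positive")
  t1 <- t1_ms %||% truth$t1_ms$values
  s0 <- truth$s0_au$values
  series_from_maps(truth, "repetition_time", sort(tr_list),
                   function(tr) s0 * (1 - exp(-tr / t1)),
                   noise_sd, seed, "sim-t1", rician)
}

#' Forward-simulate a multi-echo T2 mapping series
#'
#' Spin-echo decay `SI(TE) = s0 * exp(-TE/T2)` per voxel.
#'
#' @inheritParams simulate_t1_series
#' @param te_list echo times in ms (ascending).
#' @return an [image_series()] along `echo_time`.
#' @export
simulate_t2_series <- function(truth, te_list = default_te_ms(), noise_sd = 0,
                               seed = 1, rician = FALSE) {
  if (any(te_list <= 0)) stop("te_list must be positive")
  t2 <- truth$t2_ms$values
  s0 <- truth$s0_au$values
  series_from_maps(truth, "echo_time", sort(te_list),
                   function(te) s0 * exp(-te / t2),
                   noise_sd, seed, "sim-t2", rician)
}

#' Forward-simulate a multi-b diffusion-weighted series
#'
#' Mono-exponential decay `S(b) = s0 * exp(-b * ADC)` per voxel.
#'
#' @inheritParams simulate_t1_series
#' @param b_values diffusion weightings in s/mm^2 (nonnegative, ascending).
#' @return an [image_series()] along `b_value`.
#' @export
simulate_dwi_series <- function(truth, b_values = default_b_values(),
                                noise_sd = 0, seed = 1, rician = FALSE) {
  if (any(b_values < 0)) stop("b_values must be nonnegative")
  adc <- truth$adc_mm2_per_s$values
  s0 <- truth$s0_au$values
  series_from_maps(truth, "b_value", sort(b_values),
                   function(b) s0 * exp(-b * adc),
                   noise_sd, seed, "sim-dwi", rician)
}

#' Forward-simulate a dynamic contrast-enhanced series
#'
#' Generates per-voxel tissue concentration curves from the ground-truth
#' extended Tofts parameters and the population arterial input function,
#' then maps concentration to spoiled-gradient-echo signal with the same
#' relaxivity conversion that [signal_to_concentration()] inverts. Frames
#' before the injection time carry no enhancement in expectation.
#'
#' @inheritParams simulate_t1_series
#' @param timing a [dce_timing()].
#' @param aif an [aif_model()].
#' @param conversion a [dce_conversion()] (relaxivity, flip angle, TR).
#' @return an [image_series()] along `dynamic_time`.
#' @export
simulate_dce_series <- function(truth, timing = dce_timing(),
                                aif = aif_model(),
                                conversion = dce_conversion(),
                                noise_sd = 0, seed = 1, rician = FALSE) {
  stopifnot(inherits(timing, "dce_timing"))
  cp <- population_aif(timing, aif)
  t_s <- cp$times_s
  kt <- as.vector(truth$ktrans_per_min$values)
  ve <- as.vector(truth$ve_frac$values)
  vp <- as.vector(truth$vp_frac$values)
  # voxels sharing identical PK parameters (the constant background) need
  # only one forward evaluation of the convolution
  t1_pre <- as.vector(truth$t1_ms$values)                 # ms
  key <- paste(kt, ve, vp, t1_pre)
  uniq <- which(!duplicated(key))
  ct_u <- tofts_forward_matrix(t_s, cp$values, kt[uniq], ve[uniq], vp[uniq])
  r1_u <- rep(1000 / t1_pre[uniq], each = length(t_s)) + conversion$r1 * ct_u
  g_u <- spgr_signal(r1_u, 1, conversion)                 # unit-m0 signal
  nr <- nrow(truth$tumor_mask$grid); nc <- ncol(truth$tumor_mask$grid)
  # voxel-major layout (N x nt) maps straight onto (nr, nc, nt)
  frames <- t(g_u)[match(key, key[uniq]), , drop = FALSE] *
    as.vector(truth$s0_au$values)
  set.seed(derive_seed(seed, "sim-dce"))
  frames <- add_noise(frames, noise_sd, rician)
  dim(frames) <- c(nr, nc, length(t_s))
  new_image_series(frames, "dynamic_time", t_s,
                   pixel_spacing = truth$pixel_spacing,
                   slice_thickness = truth$slice_thickness)
}

#' Forward-simulate a laser-ablation ICP-MS experiment
#'
#' Produces (i) a calibration-standard table with replicate line-mean
#' intensities per concentration level, mean `intercept + sensitivity *
#' concentration` and heteroscedastic noise `sd = blank_sd * (1 + h * conc)`,
#' and (ii) a line-by-line scan over the tumor's bounding box at the laser
#' spot spacing, sampling the ground-truth Gd map by nearest voxel.
#'
#' @param truth a `phantom_truth`.
#' @param standard_levels gelatin standard concentrations (mg/L), must
#'   include a blank (0).
#' @param sensitivity detector counts per (ug/g).
#' @param blank_sd replicate noise sd at the blank level (counts).
#' @param heteroscedasticity relative sd growth per concentration unit.
#' @param intercept background count level.
#' @param n_replicates ablated lines per standard.
#' @param spot_size_um laser spot size (and spot spacing), micrometers.
#' @param scan_speed_um_per_s scan speed, micrometers per second.
#' @param seed integer seed.
#' @param element `"Gd"` or `"Fe"`.
#' @return list with `standards` (data.frame: concentration, replicate,
#'   intensity) and `linescan` (intensity matrix with spot geometry and the
#'   voxel index mapping used for sampling).
#' @export
simulate_laicpms_experiment <- function(truth,
                                        standard_levels = seq(0, 600, by = 100),
                                        sensitivity = 10, blank_sd = 2,
                                        heteroscedasticity = 0.005,
                                        intercept = 50, n_replicates = 10,
                                        spot_size_um = 15,
                                        scan_speed_um_per_s = 30,
                                        seed = 1, element = "Gd") {
  if (!any(standard_levels == 0)) stop("standard_levels must include a blank (0)")
  if (sensitivity <= 0) stop("sensitivity must be > 0")
  set.seed(derive_seed(seed, paste0("laicpms-", element)))
  standards <- do.call(rbind, lapply(standard_levels, function(lv) {
    mu <- intercept + sensitivity * lv
    sdv <- blank_sd * (1 + heteroscedasticity * lv)
    data.frame(concentration = lv, replicate = seq_len(n_replicates),
               intensity = pmax(mu + stats::rnorm(n_replicates, 0, sdv), 0))
  }))

  # line scan over the tumor bounding box at spot-size spacing
  g <- truth$tumor_mask$grid
  rows <- range(which(rowSums(g) > 0))
  cols <- range(which(colSums(g) > 0))
  h_um <- (rows[2] - rows[1] + 1) * truth$pixel_spacing[1] * 1000
  w_um <- (cols[2] - cols[1] + 1) * truth$pixel_spacing[2] * 1000
  n_lines <- ceiling(h_um / spot_size_um)
  n_spots <- ceiling(w_um / spot_size_um)
  # nearest source voxel per spot center
  row_voxel <- rows[1] + pmin(floor(((seq_len(n_lines) - 0.5) * spot_size_um) /
                                      (truth$pixel_spacing[1] * 1000)),
                              rows[2] - rows[1])
  col_voxel <- cols[1] + pmin(floor(((seq_len(n_spots) - 0.5) * spot_size_um) /
                                      (truth$pixel_spacing[2] * 1000)),
                              cols[2] - cols[1])
  gd <- truth$gd_ug_per_g$values[row_voxel, col_voxel, drop = FALSE]
  mu <- intercept + sensitivity * gd
  sdv <- blank_sd * (1 + heteroscedasticity * gd)
  intensity <- matrix(pmax(mu + stats::rnorm(length(mu), 0, sdv), 0),
                      n_lines, n_spots)
  list(standards = standards,
       linescan = list(intensity = intensity, element = element,
                       spot_size_um = spot_size_um,
                       scan_speed_um_per_s = scan_speed_um_per_s,
                       row_voxel = row_voxel, col_voxel = col_voxel))
}

#' Generate a study cohort of phantoms
#'
#' One tumor per phenotype, day and replicate, each with a distinct seed
#' derived from the master seed, plus a manifest listing them.
#'
#' @param n_per_group tumors per phenotype per day (>= 2).
#' @param days measurement days.
#' @param seed master seed.
#' @param ... forwarded to [make_phantom()] (grid, ranges, geometry).
#' @return list with `phantoms` (list of `phantom_truth`) and `manifest`
#'   (data.frame: tumor_id, phenotype, day, seed).
#' @export
make_cohort <- function(n_per_group = 8, days = c(3, 6, 9), seed = 42, ...) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  rows <- expand.grid(replicate = seq_len(n_per_group), day = days,
                      phenotype = PHENOTYPES, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  manifest <- data.frame(
    tumor_id = sprintf("%s_d%d_%02d",
                       ifelse(rows$phenotype == PHENOTYPES[1], "het", "hom"),
                       rows$day, rows$replicate),
    phenotype = rows$phenotype, day = rows$day,
    seed = mapply(function(p, d, i) derive_seed(seed, paste(p, d, i)),
                  rows$phenotype, rows$day, rows$replicate,
                  USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$seed))
    manifest$seed <- manifest$seed + seq_len(nrow(manifest)) - 1L
  phantoms <- lapply(seq_len(nrow(manifest)), function(i)
    make_phantom(manifest$phenotype[i], manifest$day[i],
                 seed = manifest$seed[i], ...))
  names(phantoms) <- manifest$tumor_id
  structure(list(phantoms = phantoms, manifest = manifest),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d tumors (%s)\n", nrow(x$manifest),
              paste(unique(x$manifest$day), collapse = "/")))
  invisible(x)
}
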