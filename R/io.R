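# File interfaces: NIfTI volumes with JSON sidecars for image series and
# parameter maps, CSV manifests and feature tables, YAML study configs.

#' Write / read an image series as NIfTI plus JSON sidecar
#'
#' NIfTI has no native convention for a b-value/TR/TE axis, so the frames
#' are stored as a 3D volume (rows x cols x frames) and the axis kind,
#' axis values and voxel geometry go into a JSON sidecar next to it.
#'
#' @param series an [image_series()].
#' @param path output path ending in `.nii` or `.nii.gz`; the sidecar is
#'   written with extension `.json`.
#' @return `write_image_series()`: the path, invisibly.
#'   `read_image_series()`: the reconstructed [image_series()].
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  RNifti::writeNifti(RNifti::asNifti(series$frames), path)
  sidecar <- list(axis_kind = series$axis_kind,
                  axis_values = series$axis_values,
                  pixel_spacing = series$pixel_spacing,
                  slice_thickness = series$slice_thickness)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname write_image_series
#' @param path path of the `.nii`/`.nii.gz` file written earlier.
#' @export
read_image_series <- function(path) {
  frames <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  image_series(array(frames, dim(frames)), meta$axis_kind, meta$axis_values,
               meta$pixel_spacing, meta$slice_thickness)
}

#' Write / read a parameter map as NIfTI plus JSON sidecar
#'
#' The values go into the NIfTI volume (invalid voxels as NaN); name,
#' units and the validity mask (run-length-free 0/1 vector) go into the
#' sidecar.
#'
#' @param map a [parameter_map()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return the path / the reconstructed [parameter_map()].
#' @export
write_parameter_map <- function(map, path) {
  stopifnot(inherits(map, "parameter_map"))
  vals <- map$values
  vals[!map$valid] <- NaN
  RNifti::writeNifti(RNifti::asNifti(array(vals, c(dim(vals), 1))), path)
  sidecar <- list(name = map$name, units = map$units,
                  valid = as.integer(map$valid), dim = dim(map$values))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_parameter_map
#' @export
read_parameter_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  vals <- matrix(arr, meta$dim[1], meta$dim[2])
  valid <- matrix(meta$valid == 1, meta$dim[1], meta$dim[2])
  vals[!valid] <- NA_real_
  parameter_map(vals, meta$name, meta$units, valid)
}

#' Write / read a cohort manifest as CSV
#'
#' @param manifest the manifest data.frame from [make_cohort()].
#' @param path CSV path.
#' @return the path / the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a study configuration to YAML (and back)
#'
#' @param config a [study_config()].
#' @param path YAML path.
#' @return the path / the reconstructed [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- study_config()
  for (nm in names(raw)) {
    cur <- cfg[[nm]]
    if (inherits(cur, c("dce_timing", "aif_model", "dce_conversion",
                        "fit_config", "histogram_config",
                        "tofts_fit_config"))) {
      cfg[[nm]] <- structure(utils::modifyList(unclass(cur), raw[[nm]]),
                             class = class(cur))
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

#' Write the study report tables to a directory
#'
#' Emits `feature_table.csv`, `comparisons.csv`, `manifest.csv`,
#' `pca_variance.csv`, and `report.json` (accuracy, correlation, config
#' echo with master seed).
#'
#' @param report a [run_study()] result.
#' @param out_dir directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$feature_table,
                   file.path(out_dir, "feature_table.csv"), row.names = FALSE)
  utils::write.csv(report$comparisons,
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  write_manifest(report$manifest, file.path(out_dir, "manifest.csv"))
  pv <- do.call(rbind, lapply(names(report$pca), function(nm)
    data.frame(scope = nm,
               component = seq_along(report$pca[[nm]]$variance_ratio),
               variance_ratio = report$pca[[nm]]$variance_ratio)))
  utils::write.csv(pv, file.path(out_dir, "pca_variance.csv"),
                   row.names = FALSE)
  summary <- list(
    n_tumors = nrow(report$feature_table),
    pc1_accuracy = as.list(report$pc1_accuracy),
    correlation = if (!is.null(report$correlation))
      list(r = report$correlation$statistic,
           p = report$correlation$p_value),
    master_seed = report$config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
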