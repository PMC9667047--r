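# Domain containers: image series, ROI masks, parameter maps.

AXIS_KINDS <- c("b_value", "repetition_time", "echo_time", "dynamic_time")

#' Stack of 2D frames along an acquisition axis
#'
#' An `image_series` holds a single-slice acquisition as a 3D array
#' (rows x cols x frames) together with the acquisition axis: b-values
#' (s/mm^2) for diffusion weighting, repetition times (ms) for T1 mapping,
#' echo times (ms) for T2 mapping, or dynamic frame times (s) for DCE.
#'
#' @param frames numeric 3D array `nr x nc x n_frames`, all values >= 0.
#' @param axis_kind one of `"b_value"`, `"repetition_time"`, `"echo_time"`,
#'   `"dynamic_time"`.
#' @param axis_values numeric vector, one strictly increasing value per frame.
#' @param pixel_spacing in-plane voxel edge lengths in mm (length 2).
#' @param slice_thickness slice thickness in mm.
#' @return an object of class `image_series`.
#' @export
image_series <- function(frames, axis_kind, axis_values,
                         pixel_spacing = c(0.28, 0.28), slice_thickness = 1) {
  axis_kind <- match.arg(axis_kind, AXIS_KINDS)
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3D array (rows x cols x frames)")
  n <- dim(frames)[3]
  if (length(axis_values) != n || n < 1L)
    stop("length(axis_values) must equal the number of frames (>= 1)")
  if (n > 1L && any(diff(axis_values) <= 0))
    stop("axis_values must be strictly increasing")
  if (any(frames < 0, na.rm = TRUE))
    stop("all intensities must be >= 0")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two positive values (mm)")
  new_image_series(frames, axis_kind, axis_values, pixel_spacing,
                   slice_thickness)
}

# internal constructor without revalidation (simulators guarantee the
# invariants by construction)
new_image_series <- function(frames, axis_kind, axis_values, pixel_spacing,
                             slice_thickness) {
  structure(
    list(frames = frames, axis_kind = axis_kind,
         axis_values = as.numeric(axis_values),
         pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness)),
    class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_series> %d x %d, %d frames along %s (%s .. %s)\n",
              d[1], d[2], d[3], x$axis_kind,
              format(min(x$axis_values)), format(max(x$axis_values))))
  invisible(x)
}

#' @export
dim.image_series <- function(x) dim(x$frames)

#' Binary region-of-interest mask
#'
#' @param grid logical (or 0/1) matrix; `TRUE` marks voxels inside the ROI.
#' @param label short text label.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(grid, label = "tumor") {
  grid <- matrix(as.logical(grid), nrow = nrow(grid), ncol = ncol(grid))
  structure(list(grid = grid, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d / %d voxels set\n",
              x$label, sum(x$grid), length(x$grid)))
  invisible(x)
}

n_voxels <- function(mask) sum(mask$grid)

check_mask <- function(mask, ref_dim) {
  stopifnot(inherits(mask, "roi_mask"))
  if (n_voxels(mask) < 1L) stop("ROI mask is empty")
  if (!is.null(ref_dim) && !identical(dim(mask$grid), ref_dim[1:2]))
    stop("ROI mask dimensions do not match the image grid")
  invisible(mask)
}

#' Voxel-wise fitted parameter map
#'
#' Holds one fitted quantity per voxel together with a validity mask marking
#' where the fit succeeded (finite estimate, amplitude above zero, no bound
#' hit) and an optional per-voxel residual RMSE.
#'
#' @param values numeric matrix of parameter values.
#' @param name short parameter name, e.g. `"T1"`, `"ADC"`.
#' @param units unit string, e.g. `"ms"`, `"mm^2/s"`.
#' @param valid logical matrix of the same shape; defaults to all finite.
#' @param fit_rmse optional numeric matrix of per-voxel fit RMSE.
#' @return an object of class `parameter_map`.
#' @export
parameter_map <- function(values, name, units, valid = NULL, fit_rmse = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(valid)) valid <- is.finite(values)
  valid <- matrix(as.logical(valid), nrow(values), ncol(values))
  if (any(!is.finite(values[valid])))
    stop("parameter values must be finite wherever marked valid")
  structure(list(values = values, name = name, units = units,
                 valid = valid, fit_rmse = fit_rmse),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<parameter_map> %s [%s], %d x %d, %d valid voxels",
              x$name, x$units, nrow(x$values), ncol(x$values), sum(x$valid)))
  if (length(v))
    cat(sprintf(", range %.4g .. %.4g", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Sampled concentration (or enhancement) curve
#'
#' @param times_s increasing sample times in seconds.
#' @param values concentration in mM, or dimensionless relative enhancement.
#' @param kind free-text label (`"concentration"` or `"enhancement"`).
#' @return an object of class `concentration_curve`.
#' @export
concentration_curve <- function(times_s, values, kind = "concentration") {
  stopifnot(length(times_s) == length(values))
  if (length(times_s) > 1L && any(diff(times_s) <= 0))
    stop("times_s must be strictly increasing")
  if (any(!is.finite(values))) stop("curve values must be finite")
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 kind = kind),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve> %s, %d samples over %.1f s, max %.4g\n",
              x$kind, length(x$times_s), diff(range(x$times_s)),
              max(x$values)))
  invisible(x)
}
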