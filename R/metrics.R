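# All three metrics share one axial dispersion functional: with T the
# (weighted) mean dyadic tensor of unit axial vectors and lambda1 its
# largest eigenvalue, dispersion = 1 - sqrt((3*lambda1 - 1)/2). lambda1 is
# 1 for perfectly aligned axes (dispersion 0) and 1/3 under isotropy
# (dispersion 1); lambda1 >= 1/3 keeps the radicand non-negative.

#' Directional variance
#'
#' Voxel-wise alignment of fibers: for each on-mask voxel the
#' confidence-weighted dyadic tensor of the axial orientation vectors of
#' all on-mask voxels within a spherical physical window is formed, and
#' the variance is `1 - sqrt((3*lambda1 - 1)/2)` of its largest eigenvalue.
#' Lower values correspond to more highly aligned fibers; values approach
#' 1 for random (isotropic) alignment.
#'
#' @param orient an `orientation_field`.
#' @param window_radius spherical window radius in micrometres.
#' @param min_count windows holding fewer on-mask voxels are undefined (NaN).
#' @return A [metric_field()] with `metric = "variance"`.
#' @export
directional_variance <- function(orient, window_radius = 5, min_count = 3) {
  d <- dim(orient$theta)
  w <- orient$confidence
  w[!is.finite(w)] <- 0
  v <- cpp_directional_variance(orient$ux, orient$uy, orient$uz, w,
                                orient$valid, d, orient$pitch,
                                window_radius, as.integer(min_count))
  metric_field(v, "variance", orient$mask,
               params = list(window_radius = window_radius,
                             min_count = min_count))
}

#' Waviness
#'
#' Voxel-wise crimp: from each on-mask voxel a path is traced
#' bidirectionally along the local axial orientation (re-reading the
#' orientation at every step, with the sign chosen to minimize turning)
#' up to a total path length `trace_length` or until the path leaves the
#' mask. The waviness is the axial dispersion of the orientations sampled
#' along the path - the same eigen-based functional as directional
#' variance, but taken along the fiber path rather than across a spatial
#' ball. Straight fibers give 0; higher values mean curvier fibers.
#'
#' @param orient an `orientation_field`.
#' @param trace_length total path length L in micrometres.
#' @param step tracing step in micrometres (default half the smallest
#'   voxel pitch; positions step continuously, orientations are looked up
#'   at the nearest voxel).
#' @return A [metric_field()] with `metric = "waviness"`; voxels whose
#'   trace collects fewer than 3 samples are undefined.
#' @export
waviness <- function(orient, trace_length = 10, step = NULL) {
  step <- step %||% (0.5 * min(orient$pitch))
  d <- dim(orient$theta)
  wv <- cpp_trace_waviness(orient$ux, orient$uy, orient$uz, orient$valid,
                           d, orient$pitch, trace_length, step)
  metric_field(wv, "waviness", orient$mask,
               params = list(trace_length = trace_length, step = step))
}

#' Local coverage
#'
#' Voxel-wise localized fiber density: for each on-mask voxel, the
#' fraction of on-mask voxels among the in-bounds voxels of a spherical
#' physical window. Values lie in `(0, 1]`, higher meaning morphologically
#' denser fiber distribution in the local area.
#'
#' @param mask a `fiber_mask` (or an `orientation_field`, whose mask is
#'   used).
#' @param window_radius window radius in micrometres.
#' @param shape `"sphere"` (Euclidean ball, the default used throughout)
#'   or `"cube"` (Chebyshev ball, e.g. a 5x5x5 voxel box at unit pitch and
#'   radius 2).
#' @return A [metric_field()] with `metric = "coverage"`, defined on mask
#'   voxels.
#' @export
local_coverage <- function(mask, window_radius = 5,
                           shape = c("sphere", "cube")) {
  shape <- match.arg(shape)
  if (inherits(mask, "orientation_field"))
    mask <- mask$mask
  if (!any(mask$voxels)) stopf("mask is empty")
  v <- cpp_local_coverage(mask$voxels, dim(mask$voxels), mask$pitch,
                          window_radius, shape == "cube")
  metric_field(v, "coverage", mask,
               params = list(window_radius = window_radius, shape = shape))
}

#' Probability distribution of a metric field
#'
#' Histogram over `[0, 1]` of the defined (on-mask) voxels, normalized to
#' probabilities.
#'
#' @param field a [metric_field()].
#' @param bins number of equal-width bins over `[0, 1]`.
#' @return Object of class `metric_distribution`: `edges` (length
#'   `bins + 1`), `probabilities` (summing to 1), `n_voxels`, `metric`.
#' @export
metric_histogram <- function(field, bins = 50) {
  v <- field$values[is.finite(field$values)]
  if (!length(v)) stopf("metric field has no defined voxels")
  idx <- pmin(floor(v * bins) + 1L, bins)  # value 1 falls in the top bin
  counts <- tabulate(idx, nbins = bins)
  structure(list(edges = seq(0, 1, length.out = bins + 1),
                 probabilities = counts / length(v),
                 n_voxels = length(v), metric = field$metric),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  mode_bin <- which.max(x$probabilities)
  cat(sprintf("<metric_distribution> %s over %d voxels, modal bin [%.2f, %.2f)\n",
              x$metric, x$n_voxels, x$edges[mode_bin], x$edges[mode_bin + 1]))
  invisible(x)
}

#' Canonical feature names, in the conventional 1..6 order
#'
#' 1 directional variance, 2 waviness, 3 local coverage of collagen;
#' 4 directional variance, 5 waviness, 6 local coverage of elastin.
#'
#' @return Character vector of six feature names.
#' @export
feature_names <- function() {
  c("variance_collagen", "waviness_collagen", "coverage_collagen",
    "variance_elastin", "waviness_elastin", "coverage_elastin")
}

#' Summarize one sample's six metric fields into a feature vector
#'
#' @param fields named list with entries `variance_collagen`,
#'   `waviness_collagen`, `coverage_collagen`, `variance_elastin`,
#'   `waviness_elastin`, `coverage_elastin`, each a [metric_field()].
#' @param statistic `"mean"` or `"median"` over the defined voxels.
#' @param sample_id,group metadata carried into the row.
#' @return One-row data frame: `sample_id`, `group`, the six features, and
#'   a `statistic` attribute.
#' @export
summarize_sample <- function(fields, statistic = c("mean", "median"),
                             sample_id = "sample", group = NA_character_) {
  statistic <- match.arg(statistic)
  need <- feature_names()
  if (!all(need %in% names(fields)))
    stopf("missing metric fields: %s",
          paste(setdiff(need, names(fields)), collapse = ", "))
  f <- if (statistic == "mean") mean else median
  vals <- vapply(need, function(nm) {
    v <- fields[[nm]]$values
    v <- v[is.finite(v)]
    if (!length(v)) stopf("metric field %s is fully undefined", nm)
    f(v)
  }, numeric(1))
  out <- data.frame(sample_id = sample_id, group = group, t(vals))
  names(out) <- c("sample_id", "group", need)
  attr(out, "statistic") <- statistic
  out
}

#' Contrast 3D analysis of a stack with 2D analysis of its projection
#'
#' Crops the stack to an ROI, computes directional variance (and waviness)
#' from the full 3D orientation field, and repeats the analysis on the
#' maximum-intensity xy projection using in-plane angles only. Crimp or
#' misalignment that lives along z is invisible to the 2D analysis.
#'
#' @param stack an [intensity_stack()].
#' @param roi optional ROI (index ranges `x`, `y`, `z`); default whole stack.
#' @param window_radius orientation window R (um).
#' @param variance_radius variance window radius (um).
#' @param trace_length waviness path length (um).
#' @param mask_param fixed-fraction mask parameter.
#' @param metrics which metrics to compare.
#' @return List with `metric_3d`, `metric_2d` (lists of [metric_field()]),
#'   `median_3d`, `median_2d` (named numerics) and histograms of each.
#' @export
compare_2d_3d <- function(stack, roi = NULL, window_radius = 2,
                          variance_radius = 5, trace_length = 10,
                          mask_param = 0.1,
                          metrics = c("variance", "waviness")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(roi)) stack <- crop_stack(stack, roi)
  m3 <- foreground_mask(stack, "fixed_fraction", mask_param, denoise = FALSE)
  o3 <- orientation_field(stack, window_radius, m3)
  proj <- project_stack(stack, "z", "max")
  o2 <- orientation_field_2d(proj, stack$pitch[1:2], window_radius,
                             mask = proj >= mask_param * max(proj) & proj > 0)
  f3 <- f2 <- list()
  if ("variance" %in% metrics) {
    f3$variance <- directional_variance(o3, variance_radius)
    f2$variance <- directional_variance(o2, variance_radius)
  }
  if ("waviness" %in% metrics) {
    f3$waviness <- waviness(o3, trace_length)
    f2$waviness <- waviness(o2, trace_length)
  }
  med <- function(f) vapply(f, function(x)
    median(x$values[is.finite(x$values)]), numeric(1))
  list(metric_3d = f3, metric_2d = f2,
       median_3d = med(f3), median_2d = med(f2),
       hist_3d = lapply(f3, metric_histogram),
       hist_2d = lapply(f2, metric_histogram))
}
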