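## ROI fluorescence-intensity measurement: per-slice -> per-neuron ->
## per-cluster -> whole brain.  Pixel membership rule: a pixel belongs to an
## ROI iff its center lies strictly inside the polygon by the even-odd rule
## (0-based pixel-center coordinates).  This makes ZEN-style "draw a contour,
## read mean/area/sum" measurements bit-reproducible.

roi_pixel_members <- function(stack, roi) {
  d <- dim(stack$voxels)
  vx <- roi$polygon[, 1]; vy <- roi$polygon[, 2]
  xr <- max(0L, ceiling(min(vx))):min(d[3] - 1L, floor(max(vx)))
  yr <- max(0L, ceiling(min(vy))):min(d[2] - 1L, floor(max(vy)))
  if (min(vx) > d[3] - 1 || max(vx) < 0 || min(vy) > d[2] - 1 || max(vy) < 0) {
    stop("empty ROI: polygon lies outside the image")
  }
  grid <- expand.grid(x = xr, y = yr)
  inside <- points_in_polygon(grid$x, grid$y, roi$polygon)
  if (!any(inside)) stop("empty ROI: polygon contains no pixel centers")
  grid[inside, , drop = FALSE]
}

#' Measure an ROI on a single slice
#'
#' Returns the quantities the assay records per optical section: pixel area,
#' calibrated area, intensity sum and intensity mean within the contour.
#'
#' @param stack A [zstack].
#' @param roi A [roi_contour]; `slice_index` must lie in its z-window.
#' @param slice_index 0-based slice index.
#' @param subtract_background `"none"` (default; raw sums, as in the vendor
#'   workflow) or `"median"` (subtract the slice-wide median intensity from
#'   each member pixel before summing).
#' @return One-row data.frame: `slice_index`, `area_px`, `area_um2`,
#'   `intensity_sum`, `intensity_mean`.
#' @export
measure_roi_slice <- function(stack, roi, slice_index,
                              subtract_background = c("none", "median"),
                              .members = NULL, .background = NULL) {
  stopifnot(inherits(stack, "zstack"), inherits(roi, "roi_contour"))
  subtract_background <- match.arg(subtract_background)
  assert_number(slice_index, "slice_index", nonneg = TRUE, integer = TRUE)
  if (slice_index < roi$z_first || slice_index > roi$z_last) {
    stop("slice_index outside the ROI z-window")
  }
  if (slice_index >= n_slices(stack)) {
    stop("slice_index exceeds stack depth")
  }
  mem <- .members %||% roi_pixel_members(stack, roi)
  vals <- stack$voxels[cbind(slice_index + 1L, mem$y + 1L, mem$x + 1L)]
  if (subtract_background == "median") {
    bg <- .background %||% stats::median(stack$voxels[slice_index + 1L, , ])
    vals <- vals - bg
  }
  area_px <- length(vals)
  s <- sum(vals)
  data.frame(slice_index = slice_index, area_px = area_px,
             area_um2 = area_px * stack$pixel_size_um^2,
             intensity_sum = s, intensity_mean = s / area_px)
}

#' Measure a neuron across its z-window
#'
#' Applies the contour to every slice in `[z_first, z_last]` (the protocol
#' default is an 11-slice window at 1.08 um spacing) and accumulates the
#' per-slice intensity sums into the neuron's fluorescence intensity (FI).
#' By default the same polygon is reused on every slice; per-slice polygons
#' may be supplied for workflows that redraw the contour on each section.
#'
#' @inheritParams measure_roi_slice
#' @param polygons Optional list of per-slice vertex matrices, one per slice
#'   in the z-window, overriding the ROI polygon slice by slice.
#' @param .slice_medians Internal: precomputed per-slice medians (used by
#'   [quantify_brain()] to avoid recomputation).
#' @return An object of class `neuron_measurement`: `neuron_id`, `cluster`,
#'   `hemisphere`, per-slice measurement table, `neuron_fi`, `n_slices`.
#' @export
measure_neuron <- function(stack, roi,
                           subtract_background = c("none", "median"),
                           polygons = NULL, .slice_medians = NULL) {
  stopifnot(inherits(stack, "zstack"), inherits(roi, "roi_contour"))
  subtract_background <- match.arg(subtract_background)
  if (roi$z_last >= n_slices(stack)) {
    stop("ROI z-window exceeds stack depth")
  }
  zw <- roi$z_first:roi$z_last
  if (!is.null(polygons) && length(polygons) != length(zw)) {
    stop("'polygons' must supply one polygon per slice in the z-window")
  }
  members <- if (is.null(polygons)) roi_pixel_members(stack, roi) else NULL
  rows <- lapply(seq_along(zw), function(i) {
    r <- roi
    if (!is.null(polygons)) r$polygon <- as.matrix(polygons[[i]])
    measure_roi_slice(stack, r, zw[i], subtract_background,
                      .members = members,
                      .background = .slice_medians[zw[i] + 1L])
  })
  slices <- do.call(rbind, rows)
  structure(
    list(neuron_id = roi$neuron_id, cluster = roi$cluster,
         hemisphere = roi$hemisphere, slices = slices,
         neuron_fi = sum(slices$intensity_sum), n_slices = length(zw)),
    class = "neuron_measurement")
}

#' Aggregate neuron measurements into a brain summary
#'
#' Cluster FI is the sum of neuron FIs within the cluster; whole-brain total
#' FI is the sum over all measured clusters.
#'
#' @param measurements List of `neuron_measurement` objects.
#' @param brain_id,condition Sample annotations.
#' @return An object of class `brain_summary` with a per-cluster table
#'   (`cluster`, `neuron_count`, `cluster_fi`), `total_fi`, `total_neurons`.
#' @export
summarize_brain <- function(measurements, brain_id = NA_character_,
                            condition = NA_character_) {
  if (length(measurements) == 0L) {
    clusters <- data.frame(cluster = character(), neuron_count = integer(),
                           cluster_fi = numeric())
    return(structure(list(brain_id = brain_id, condition = condition,
                          clusters = clusters, total_fi = 0,
                          total_neurons = 0L),
                     class = "brain_summary"))
  }
  cl <- vapply(measurements, `[[`, "", "cluster")
  fi <- vapply(measurements, `[[`, 0, "neuron_fi")
  agg <- aggregate(fi, by = list(cluster = cl), FUN = sum)
  cnt <- as.data.frame(table(cluster = cl), stringsAsFactors = FALSE)
  clusters <- merge(cnt, agg, by = "cluster")
  names(clusters) <- c("cluster", "neuron_count", "cluster_fi")
  clusters <- clusters[order(match(clusters$cluster, ALL_CLUSTERS)), ]
  rownames(clusters) <- NULL
  structure(
    list(brain_id = brain_id, condition = condition, clusters = clusters,
         total_fi = sum(fi), total_neurons = length(measurements)),
    class = "brain_summary")
}

#' @export
print.brain_summary <- function(x, ...) {
  cat(sprintf("<brain_summary> %s (%s): %d neurons, total FI %.4g\n",
              x$brain_id, x$condition, x$total_neurons, x$total_fi))
  print(x$clusters, ...)
  invisible(x)
}

#' Quantify a whole brain from a stack and its ROI set
#'
#' Convenience wrapper: measures every ROI and aggregates.
#'
#' @inheritParams measure_neuron
#' @param rois List of [roi_contour].
#' @param brain_id,condition Annotations (default from the stack).
#' @return A [summarize_brain()] result.
#' @export
quantify_brain <- function(stack, rois,
                           subtract_background = c("none", "median"),
                           brain_id = NULL, condition = NULL) {
  subtract_background <- match.arg(subtract_background)
  med <- if (subtract_background == "median") {
    vapply(seq_len(n_slices(stack)),
           function(z) stats::median(stack$voxels[z, , ]), 0)
  } else NULL
  ms <- lapply(rois, function(r) {
    measure_neuron(stack, r, subtract_background = subtract_background,
                   .slice_medians = med)
  })
  summarize_brain(ms, brain_id = brain_id %||% stack$brain_id %||% NA,
                  condition = condition %||% stack$condition %||% NA)
}
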