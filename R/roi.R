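QUANTIFIABLE_CLUSTERS <- c("PAL", "PPL1", "PPL2", "PPM1/2", "PPM3")
ALL_CLUSTERS <- c(QUANTIFIABLE_CLUSTERS, "PAM", "VUM")

#' Construct an ROI contour naming one neuron
#'
#' The measurement unit of the FI assay: a closed polygon drawn around one
#' neuron in pixel coordinates, applied over an inclusive z-window (11 slices
#' by default in the acquisition protocol).  Coordinates are 0-based and
#' refer to pixel centers: pixel `(x, y)` has its center at `(x, y)`.
#'
#' @param neuron_id Identifier string.
#' @param cluster Cluster label, one of PAL, PPL1, PPL2, PPM1/2, PPM3
#'   (quantifiable) or PAM/VUM.
#' @param hemisphere `"L"` or `"R"`.
#' @param polygon Numeric matrix with columns `x`, `y` (>= 3 vertices,
#'   implicitly closed, simple).
#' @param z_first,z_last Inclusive 0-based slice indices of the z-window.
#' @return An object of class `roi_contour`.
#' @export
roi_contour <- function(neuron_id, cluster, hemisphere, polygon,
                        z_first, z_last) {
  if (!cluster %in% ALL_CLUSTERS) {
    stop(sprintf("unknown cluster '%s'", cluster))
  }
  if (!hemisphere %in% c("L", "R")) stop("hemisphere must be 'L' or 'R'")
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L || anyNA(polygon)) {
    stop("polygon must be a numeric matrix of >= 3 (x, y) vertices")
  }
  if (!polygon_is_simple(polygon)) {
    stop("polygon must be simple (non-self-intersecting)")
  }
  assert_number(z_first, "z_first", nonneg = TRUE, integer = TRUE)
  assert_number(z_last, "z_last", nonneg = TRUE, integer = TRUE)
  if (z_first > z_last) stop("z_first must be <= z_last")
  colnames(polygon) <- c("x", "y")
  structure(
    list(neuron_id = as.character(neuron_id), cluster = cluster,
         hemisphere = hemisphere, polygon = polygon,
         z_first = as.integer(z_first), z_last = as.integer(z_last)),
    class = "roi_contour")
}

#' @export
print.roi_contour <- function(x, ...) {
  cat(sprintf("<roi_contour> %s [%s %s] %d vertices, z %d..%d\n",
              x$neuron_id, x$cluster, x$hemisphere, nrow(x$polygon),
              x$z_first, x$z_last))
  invisible(x)
}

# segment-intersection test for polygon simplicity; adjacent edges share a
# vertex and are exempt
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  intersects <- function(p, q) {
    d1 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
    d2 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
    d3 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
    d4 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  if (n <= 3) return(TRUE)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (intersects(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Test points against a polygon (even-odd rule)
#'
#' Vectorized ray-crossing membership test.  A point exactly on an edge has
#' undefined membership (the assay's pixel centers are generic with respect
#' to hand- or machine-drawn contours).
#'
#' @param px,py Point coordinates.
#' @param polygon Vertex matrix with columns x, y.
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, polygon) {
  vx <- polygon[, 1]; vy <- polygon[, 2]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# regular polygon approximating a circle, used for auto-generated contours
circle_polygon <- function(cx, cy, r, n_vertices = 20L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Read ROI contours from JSON
#'
#' Schema: `{"neurons": [{"id", "cluster", "hemisphere", "z_first",
#' "z_last", "polygon": [[x, y], ...]}, ...]}` with 0-based pixel
#' coordinates and inclusive z-ranges.
#'
#' @param path JSON file.
#' @return List of [roi_contour].
#' @export
read_rois_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$neurons)) stop("ROI JSON must contain a 'neurons' array")
  nn <- obj$neurons
  lapply(seq_len(nrow(nn)), function(i) {
    roi_contour(nn$id[i], nn$cluster[i], nn$hemisphere[i],
                polygon = nn$polygon[[i]],
                z_first = nn$z_first[i], z_last = nn$z_last[i])
  })
}

#' Write ROI contours to JSON
#'
#' @param rois List of [roi_contour].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rois_json <- function(rois, path) {
  neurons <- data.frame(
    id = vapply(rois, `[[`, "", "neuron_id"),
    cluster = vapply(rois, `[[`, "", "cluster"),
    hemisphere = vapply(rois, `[[`, "", "hemisphere"),
    z_first = vapply(rois, `[[`, 0L, "z_first"),
    z_last = vapply(rois, `[[`, 0L, "z_last"))
  neurons$polygon <- lapply(rois, function(r) unname(r$polygon))
  jsonlite::write_json(list(neurons = neurons), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
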