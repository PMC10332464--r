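## Difference-of-Gaussian blob detection for neuron counting.  The original
## assay counts neurons by eye in vendor software; an automatic detector
## makes the pipeline testable end to end.  Candidates inside the PAM
## region are counted but flagged unquantifiable (high neuronal density)
## and receive no contour.

# separable Gaussian smoothing via row-normalized band matrices; constants
# map to constants even at edges, so a DoG of a flat background is zero
gauss_band <- function(n, sigma) {
  hw <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  M <- matrix(0, n, n)
  for (d in -hw:hw) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    M[cbind(i[ok], j[ok])] <- k[d + hw + 1L]
  }
  M / rowSums(M)
}

smooth_gaussian_3d <- function(vol, sigma_xy, sigma_z) {
  d <- dim(vol)
  Ky <- gauss_band(d[2], sigma_xy)
  Kx <- gauss_band(d[3], sigma_xy)
  out <- array(0, d)
  for (z in seq_len(d[1])) out[z, , ] <- Ky %*% vol[z, , ] %*% t(Kx)
  if (sigma_z > 0) {
    Kz <- gauss_band(d[1], sigma_z)
    out <- array(Kz %*% matrix(out, nrow = d[1]), d)
  }
  out
}

# torn or misoriented brains show up as clusters with zero detections
warn_empty_clusters <- function(counts, atlas) {
  for (h in unique(atlas$hemisphere)) {
    missing <- setdiff(atlas$cluster[atlas$quantifiable &
                                       atlas$hemisphere == h],
                       counts$cluster[counts$hemisphere == h])
    if (length(missing)) {
      warning(sprintf("no neurons detected in cluster(s) %s (%s); %s",
                      paste(missing, collapse = ", "), h,
                      "check for a damaged or misoriented brain"),
              call. = FALSE)
    }
  }
}

# strict-ish 26-neighborhood local maxima above a threshold
local_maxima_3d <- function(vol, threshold) {
  d <- dim(vol)
  cand <- which(vol > threshold)
  if (length(cand) == 0L) return(NULL)
  idx <- arrayInd(cand, d)
  val <- vol[cand]
  keep <- rep(TRUE, length(cand))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    z2 <- idx[, 1] + dz; y2 <- idx[, 2] + dy; x2 <- idx[, 3] + dx
    ok <- z2 >= 1 & z2 <= d[1] & y2 >= 1 & y2 <= d[2] & x2 >= 1 & x2 <= d[3]
    nb <- rep(-Inf, length(cand))
    nb[ok] <- vol[cbind(z2[ok], y2[ok], x2[ok])]
    keep <- keep & (val >= nb)
  }
  cbind(idx[keep, , drop = FALSE], response = val[keep])
}

#' Detect neurons in a z-stack against a cluster atlas
#'
#' Difference-of-Gaussian filtering (matched to the expected blob size)
#' followed by thresholded 3-D local-maximum extraction, greedy merging of
#' maxima closer than `min_sep_um`, and assignment of each surviving
#' candidate to the nearest atlas centroid within its placement radius plus
#' a margin.  Accepted neurons in quantifiable clusters receive a circular
#' contour at `roi_sigma_mult` lateral sigmas and an 11-slice z-window
#' centered on the peak slice (clipped at stack edges).  Candidates in the
#' PAM region are counted but flagged `"unquantifiable - high neuronal
#' density"` and get no contour.
#'
#' @param stack A calibrated [zstack].
#' @param atlas data.frame with columns `cluster`, `hemisphere`, `x`, `y`,
#'   `z` (voxel coordinates), `radius_um`, `quantifiable` - e.g. from
#'   [brain_atlas()].
#' @param sigma_um Expected blob sigma in micrometres.
#' @param min_peak DoG response threshold for a candidate.
#' @param min_sep_um Minimum physical separation between accepted peaks.
#' @param assign_margin_um Extra reach beyond a cluster's atlas radius when
#'   assigning candidates.
#' @param roi_sigma_mult Contour radius in lateral sigmas.
#' @param z_window Slices per neuron z-window.
#' @return An object of class `neuron_detection`: `contours` (list of
#'   [roi_contour]), `counts` (per cluster x hemisphere, quantifiable
#'   clusters), `pam_count` (flagged unquantifiable candidates),
#'   `candidates` (full table including unassigned).
#' @export
detect_neurons <- function(stack, atlas,
                           sigma_um = 1.2, min_peak = 50,
                           min_sep_um = 3, assign_margin_um = NULL,
                           roi_sigma_mult = 2.5, z_window = 11L) {
  stopifnot(inherits(stack, "zstack"))
  if (is.null(stack$pixel_size_um) || is.null(stack$z_interval_um)) {
    stop("detection requires a calibrated stack")
  }
  px <- stack$pixel_size_um
  dz_um <- stack$z_interval_um
  assign_margin_um <- assign_margin_um %||% (3 * sigma_um)
  sxy <- sigma_um / px
  szl <- sigma_um / dz_um
  g1 <- smooth_gaussian_3d(stack$voxels, sxy, szl)
  g2 <- smooth_gaussian_3d(stack$voxels, 1.6 * sxy, 1.6 * szl)
  dog <- g1 - g2
  peaks <- local_maxima_3d(dog, min_peak)
  empty <- data.frame(cluster = character(), hemisphere = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      response = numeric(), flag = character())
  if (is.null(peaks) || nrow(peaks) == 0L) {
    warn_empty_clusters(data.frame(cluster = character(),
                                   hemisphere = character(),
                                   n = integer()), atlas)
    return(structure(list(contours = list(),
                          counts = data.frame(cluster = character(),
                                              hemisphere = character(),
                                              n = integer()),
                          pam_count = 0L, candidates = empty),
                     class = "neuron_detection"))
  }
  cand <- data.frame(z = peaks[, 1] - 1, y = peaks[, 2] - 1,
                     x = peaks[, 3] - 1, response = peaks[, "response"])
  cand <- cand[order(-cand$response), ]

  # greedy non-maximum suppression in physical coordinates
  acc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(acc)) {
      dx <- (cand$x[i] - cand$x[acc]) * px
      dy <- (cand$y[i] - cand$y[acc]) * px
      dzz <- (cand$z[i] - cand$z[acc]) * dz_um
      if (any(dx^2 + dy^2 + dzz^2 < min_sep_um^2)) next
    }
    acc <- c(acc, i)
  }
  cand <- cand[acc, , drop = FALSE]

  # nearest-centroid assignment within radius + margin
  cand$cluster <- NA_character_
  cand$hemisphere <- NA_character_
  cand$flag <- NA_character_
  for (i in seq_len(nrow(cand))) {
    dx <- (cand$x[i] - atlas$x) * px
    dy <- (cand$y[i] - atlas$y) * px
    dzz <- (cand$z[i] - atlas$z) * dz_um
    dist <- sqrt(dx^2 + dy^2 + dzz^2)
    within <- dist <= atlas$radius_um + assign_margin_um
    if (!any(within)) next
    j <- which(within)[which.min(dist[within])]
    cand$cluster[i] <- atlas$cluster[j]
    cand$hemisphere[i] <- atlas$hemisphere[j]
    if (!isTRUE(atlas$quantifiable[j])) {
      cand$flag[i] <- "unquantifiable - high neuronal density"
    }
  }

  accepted <- cand[!is.na(cand$cluster) & is.na(cand$flag), , drop = FALSE]
  pam_count <- sum(cand$cluster %in% "PAM", na.rm = TRUE)
  nz <- dim(stack$voxels)[1]
  half <- (z_window - 1) %/% 2
  contours <- lapply(seq_len(nrow(accepted)), function(i) {
    z_first <- max(0L, min(as.integer(accepted$z[i] - half), nz - z_window))
    roi_contour(
      sprintf("det_%s_%s_%02d", gsub("/", "", accepted$cluster[i]),
              accepted$hemisphere[i], i),
      accepted$cluster[i], accepted$hemisphere[i],
      circle_polygon(accepted$x[i], accepted$y[i], roi_sigma_mult * sxy),
      z_first = z_first, z_last = min(nz - 1L, z_first + z_window - 1L))
  })
  counts <- if (nrow(accepted)) {
    as.data.frame(table(cluster = accepted$cluster,
                        hemisphere = accepted$hemisphere),
                  stringsAsFactors = FALSE, responseName = "n")
  } else {
    data.frame(cluster = character(), hemisphere = character(),
               n = integer())
  }
  counts <- counts[counts$n > 0, , drop = FALSE]
  rownames(counts) <- NULL
  warn_empty_clusters(counts, atlas)
  structure(list(contours = contours, counts = counts,
                 pam_count = pam_count, candidates = cand),
            class = "neuron_detection")
}

#' @export
print.neuron_detection <- function(x, ...) {
  cat(sprintf("<neuron_detection> %d quantifiable neurons, %d PAM-flagged\n",
              length(x$contours), x$pam_count))
  if (nrow(x$counts)) print(x$counts, ...)
  invisible(x)
}

#' Atlas table for detection on a generated brain
#'
#' @param config A [brain_config].
#' @return data.frame usable as the `atlas` argument of [detect_neurons()].
#' @export
brain_atlas <- function(config = brain_config()) {
  at <- atlas_table(config)
  at[, c("cluster", "hemisphere", "x", "y", "z", "radius_um",
         "quantifiable")]
}
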