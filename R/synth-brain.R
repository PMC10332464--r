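## Synthetic whole-mount brain generator.  The stated world: per hemisphere,
## five quantifiable DAergic clusters totalling exactly 40 neurons
## (PAL 5, PPL1 12, PPL2 7, PPM1/2 9, PPM3 7), a dense PAM blob of 100
## neurons that cannot be resolved per neuron, and a VUM position present in
## the atlas but not measured (count 0 by default) - 140 neurons per
## hemisphere including PAM.  Under the "treated" (PD) condition neuron
## positions and counts are untouched; per-cluster amplitudes are scaled by
## an attenuation factor (default 0.58 for PAL/PPL1/PPL2/PPM3, 1.0 for the
## spared PPM1/2), giving a closed-form quantifiable total-FI reduction of
## (31 * 0.42) / 40 = 32.55%.

#' Default cluster atlas for the synthetic brain
#'
#' Centroids are voxel coordinates of the left hemisphere of the default
#' image geometry (x in 0..159); the right hemisphere is mirrored about the
#' image midline.  Counts, radii and attenuations are package conventions
#' chosen to be consistent with the approximate census of the adult fly
#' brain (~40 quantifiable neurons, ~140 including PAM, per hemisphere).
#'
#' @return data.frame with columns `cluster`, `count`, `x`, `y`, `z`,
#'   `radius_um`, `amplitude`, `sigma_um`, `attenuation`, `quantifiable`.
#' @export
default_cluster_spec <- function() {
  data.frame(
    cluster = c("PAL", "PPL1", "PPL2", "PPM1/2", "PPM3", "PAM", "VUM"),
    count = c(5L, 12L, 7L, 9L, 7L, 100L, 0L),
    x = c(35, 30, 45, 110, 120, 120, 150),
    y = c(55, 100, 140, 150, 110, 60, 170),
    z = c(20, 20, 20, 20, 20, 20, 20),
    radius_um = c(10, 14, 12, 13, 12, 8, 6),
    amplitude = 1000,
    sigma_um = 1.2,
    attenuation = c(0.58, 0.58, 0.58, 1.0, 0.58, 0.58, 1.0),
    quantifiable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Configure the synthetic brain generator
#'
#' Defaults encode the stated world of the assay; see
#' [default_cluster_spec()].  Noise defaults: Gaussian sd = 2% of the neuron
#' peak amplitude, uniform background = 5% of peak amplitude, Poisson off.
#'
#' @param cluster_spec Atlas table as from [default_cluster_spec()].
#' @param hemispheres `c("L", "R")` (default), `"L"` or `"R"`.
#' @param image_shape `(n_slices, height, width)`; default `(40, 192, 320)`
#'   for two hemispheres, width 160 for one.
#' @param pixel_size_um,z_interval_um Physical calibration.
#' @param background_level Constant background intensity.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param poisson If `TRUE`, apply Poisson resampling of the noise-free
#'   signal before adding Gaussian noise.
#' @param min_sep_um Minimum 3-D separation between neurons of one
#'   quantifiable cluster (keeps ROIs disjoint; the PAM blob ignores it).
#' @param z_jitter_slices Half-range of uniform z placement about the
#'   cluster plane, in slices.
#' @param roi_sigma_mult Auto-contour radius in units of the lateral blob
#'   sigma (2.5 by default).
#' @param z_window Slices per neuron z-window (protocol default 11).
#' @param seed Default seed used when [generate_brain()] is not given one.
#' @return An object of class `brain_config`.
#' @export
brain_config <- function(cluster_spec = default_cluster_spec(),
                         hemispheres = c("L", "R"),
                         image_shape = NULL,
                         pixel_size_um = 0.65,
                         z_interval_um = 1.08,
                         background_level = 50,
                         noise_sd = 20,
                         poisson = FALSE,
                         min_sep_um = 7,
                         z_jitter_slices = 4,
                         roi_sigma_mult = 2.5,
                         z_window = 11L,
                         seed = 42L) {
  hemispheres <- match.arg(hemispheres, c("L", "R"), several.ok = TRUE)
  if (is.null(image_shape)) {
    image_shape <- c(40L, 192L, if (length(hemispheres) == 2L) 320L else 160L)
  }
  assert_number(image_shape, "image_shape", positive = TRUE, integer = TRUE,
                len = 3L)
  assert_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  assert_number(z_interval_um, "z_interval_um", positive = TRUE)
  assert_number(background_level, "background_level", nonneg = TRUE)
  assert_number(noise_sd, "noise_sd", nonneg = TRUE)
  assert_number(min_sep_um, "min_sep_um", nonneg = TRUE)
  assert_number(z_window, "z_window", positive = TRUE, integer = TRUE)
  req <- c("cluster", "count", "x", "y", "z", "radius_um", "amplitude",
           "sigma_um", "attenuation", "quantifiable")
  if (!all(req %in% names(cluster_spec))) {
    stop("cluster_spec is missing columns: ",
         paste(setdiff(req, names(cluster_spec)), collapse = ", "))
  }
  with(cluster_spec, {
    if (any(amplitude <= 0) || any(sigma_um <= 0) || any(count < 0)) {
      stop("cluster amplitudes and sigmas must be > 0, counts >= 0")
    }
    if (any(attenuation <= 0 | attenuation > 1)) {
      stop("attenuation factors must lie in (0, 1]")
    }
  })
  cfg <- structure(
    list(cluster_spec = cluster_spec, hemispheres = hemispheres,
         image_shape = as.integer(image_shape),
         pixel_size_um = pixel_size_um, z_interval_um = z_interval_um,
         background_level = background_level, noise_sd = noise_sd,
         poisson = isTRUE(poisson), min_sep_um = min_sep_um,
         z_jitter_slices = z_jitter_slices,
         roi_sigma_mult = roi_sigma_mult, z_window = as.integer(z_window),
         seed = as.integer(seed)),
    class = "brain_config")
  validate_brain_geometry(cfg)
  cfg
}

# mirrored centroid table, one row per (cluster, hemisphere)
atlas_table <- function(config) {
  cs <- config$cluster_spec
  w <- config$image_shape[3]
  out <- do.call(rbind, lapply(config$hemispheres, function(h) {
    a <- cs
    a$hemisphere <- h
    if (h == "R") a$x <- (w - 1) - a$x
    a
  }))
  rownames(out) <- NULL
  out
}

# reject configs whose blobs (placement radius + 4 sigma support) can leave
# the image, or whose z-windows cannot fit
validate_brain_geometry <- function(config) {
  at <- atlas_table(config)
  at <- at[at$count > 0, , drop = FALSE]
  d <- config$image_shape
  px <- config$pixel_size_um
  half <- (config$z_window - 1) / 2
  for (i in seq_len(nrow(at))) {
    r_px <- at$radius_um[i] / px + 4 * at$sigma_um[i] / px
    if (at$x[i] - r_px < 0 || at$x[i] + r_px > d[3] - 1 ||
        at$y[i] - r_px < 0 || at$y[i] + r_px > d[2] - 1) {
      stop(sprintf("cluster %s (%s): blob support falls outside the image",
                   at$cluster[i], at$hemisphere[i]))
    }
    zr <- config$z_jitter_slices + 4 * at$sigma_um[i] / config$z_interval_um
    if (at$z[i] - zr < 0 || at$z[i] + zr > d[1] - 1) {
      stop(sprintf("cluster %s (%s): blob support exceeds stack depth",
                   at$cluster[i], at$hemisphere[i]))
    }
    if (at$z[i] - config$z_jitter_slices - half < -0.5 ||
        at$z[i] + config$z_jitter_slices + half > d[1] - 0.5) {
      stop(sprintf("cluster %s (%s): z-window cannot fit in the stack",
                   at$cluster[i], at$hemisphere[i]))
    }
  }
  invisible(config)
}

# uniform placement in a disc x slab, with rejection sampling for minimum
# 3-D physical separation within the cluster
place_cluster_neurons <- function(n, cx, cy, cz, radius_um, min_sep_um,
                                  pixel_size_um, z_interval_um,
                                  z_jitter_slices) {
  xs <- ys <- zs <- numeric(n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(5000L)) {
      r <- radius_um * sqrt(stats::runif(1))
      th <- 2 * pi * stats::runif(1)
      x <- cx + r * cos(th) / pixel_size_um
      y <- cy + r * sin(th) / pixel_size_um
      z <- cz + stats::runif(1, -z_jitter_slices, z_jitter_slices)
      ok <- TRUE
      if (min_sep_um > 0 && i > 1) {
        dx <- (x - xs[seq_len(i - 1)]) * pixel_size_um
        dy <- (y - ys[seq_len(i - 1)]) * pixel_size_um
        dz <- (z - zs[seq_len(i - 1)]) * z_interval_um
        ok <- all(dx^2 + dy^2 + dz^2 >= min_sep_um^2)
      }
      if (ok) break
      if (attempt == 5000L) {
        stop("could not place neurons at the requested density; ",
             "reduce counts or min_sep_um")
      }
    }
    xs[i] <- x; ys[i] <- y; zs[i] <- z
  }
  data.frame(x = xs, y = ys, z = zs)
}

# render all blobs into one freshly allocated volume; flat-index assignment
# inside the owning frame keeps the array unshared so updates are in place
render_blobs <- function(dims, x0, y0, z0, amplitude, sigma_xy_px,
                         sigma_z_sl) {
  vol <- array(0, dims)
  n1 <- dims[1]
  n12 <- dims[1] * dims[2]
  for (i in seq_along(x0)) {
    hw <- ceiling(4 * sigma_xy_px[i])
    hz <- ceiling(4 * sigma_z_sl[i])
    xs <- max(0, floor(x0[i] - hw)):min(dims[3] - 1, ceiling(x0[i] + hw))
    ys <- max(0, floor(y0[i] - hw)):min(dims[2] - 1, ceiling(y0[i] + hw))
    zs <- max(0, floor(z0[i] - hz)):min(dims[1] - 1, ceiling(z0[i] + hz))
    gx <- exp(-(xs - x0[i])^2 / (2 * sigma_xy_px[i]^2))
    gy <- exp(-(ys - y0[i])^2 / (2 * sigma_xy_px[i]^2))
    gz <- amplitude[i] * exp(-(zs - z0[i])^2 / (2 * sigma_z_sl[i]^2))
    patch <- outer(gz, outer(gy, gx))
    idx <- outer(zs + 1, outer(ys * n1, xs * n12, "+"), "+")
    vol[idx] <- vol[idx] + patch
  }
  vol
}

#' Generate a ground-truthed synthetic brain
#'
#' Renders every neuron as a 3-D Gaussian blob (isotropic in physical
#' units) on a constant background with Gaussian read noise, and returns the
#' stack together with the ground truth (positions, per-neuron true
#' integrated signal) and auto-generated ROI contours for the quantifiable
#' neurons (circle at `roi_sigma_mult` lateral sigmas, 11-slice z-window
#' centered on the neuron).  For a fixed seed, neuron positions, counts and
#' the noise field are identical across conditions; only amplitudes change
#' (the "no neuron loss, reduced TH signal" structure).
#'
#' @param config A [brain_config].
#' @param condition `"control"` or `"treated"`; under `"treated"` each
#'   cluster's amplitude is multiplied by its attenuation factor.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with elements `stack` ([zstack]), `truth` (data.frame:
#'   `id`, `cluster`, `hemisphere`, `x`, `y`, `z`, `amplitude`, `true_fi`,
#'   `quantifiable`; attributes `condition`, `total_true_fi` = quantifiable
#'   total), and `rois` (list of [roi_contour]).
#' @export
generate_brain <- function(config = brain_config(),
                           condition = c("control", "treated"),
                           seed = NULL) {
  stopifnot(inherits(config, "brain_config"))
  condition <- match.arg(condition)
  seed <- as.integer(seed %||% config$seed)
  at <- atlas_table(config)
  px <- config$pixel_size_um
  sxy <- at$sigma_um / px
  sz <- at$sigma_um / config$z_interval_um

  with_seed(seed, {
    placed <- vector("list", nrow(at))
    for (i in seq_len(nrow(at))) {
      if (at$count[i] == 0L) next
      sep <- if (at$cluster[i] == "PAM") 0 else config$min_sep_um
      p <- place_cluster_neurons(at$count[i], at$x[i], at$y[i], at$z[i],
                                 at$radius_um[i], sep, px,
                                 config$z_interval_um,
                                 config$z_jitter_slices)
      p$cluster <- at$cluster[i]
      p$hemisphere <- at$hemisphere[i]
      p$amplitude0 <- at$amplitude[i]
      p$attenuation <- at$attenuation[i]
      p$sigma_um <- at$sigma_um[i]
      p$sigma_xy_px <- sxy[i]
      p$sigma_z_sl <- sz[i]
      p$quantifiable <- at$quantifiable[i]
      placed[[i]] <- p
    }
    truth <- do.call(rbind, placed)
    rownames(truth) <- NULL
    truth$id <- sprintf("%s_%s_%02d", gsub("/", "", truth$cluster),
                        truth$hemisphere,
                        stats::ave(seq_len(nrow(truth)),
                                   paste(truth$cluster, truth$hemisphere),
                                   FUN = seq_along))
    truth$amplitude <- truth$amplitude0 *
      if (condition == "treated") truth$attenuation else 1
    truth$true_fi <- truth$amplitude * (2 * pi)^1.5 *
      truth$sigma_xy_px^2 * truth$sigma_z_sl

    vol <- render_blobs(config$image_shape, truth$x, truth$y, truth$z,
                        truth$amplitude, truth$sigma_xy_px,
                        truth$sigma_z_sl)
    vol <- vol + config$background_level
    if (config$poisson) {
      vol[] <- stats::rpois(length(vol), pmax(vol, 0))
    }
    if (config$noise_sd > 0) {
      vol <- vol + stats::rnorm(length(vol), 0, config$noise_sd)
    }
    vol[vol < 0] <- 0

    rois <- NULL
    q <- which(truth$quantifiable)
    half <- (config$z_window - 1) %/% 2
    nz <- config$image_shape[1]
    rois <- lapply(q, function(i) {
      z0 <- round(truth$z[i])
      z_first <- max(0L, min(as.integer(z0 - half),
                             nz - config$z_window))
      roi_contour(
        truth$id[i], truth$cluster[i], truth$hemisphere[i],
        circle_polygon(truth$x[i], truth$y[i],
                       config$roi_sigma_mult * truth$sigma_xy_px[i]),
        z_first = z_first,
        z_last = min(nz - 1L, z_first + config$z_window - 1L))
    })

    truth_out <- truth[, c("id", "cluster", "hemisphere", "x", "y", "z",
                           "amplitude", "sigma_um", "true_fi",
                           "quantifiable")]
    attr(truth_out, "condition") <- condition
    attr(truth_out, "total_true_fi") <- sum(truth$true_fi[q])
    list(
      stack = zstack(vol, pixel_size_um = px,
                     z_interval_um = config$z_interval_um,
                     brain_id = sprintf("synthetic_seed%d", seed),
                     condition = condition),
      truth = truth_out,
      rois = rois)
  })
}
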