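# Small, fast brain fixtures for unit tests; acceptance tests use the
# package defaults.

small_cluster_spec <- function() {
  data.frame(
    cluster = c("PAL", "PPL1", "PPM3"),
    count = c(2L, 3L, 2L),
    x = c(20, 48, 20), y = c(20, 40, 60), z = c(12, 12, 12),
    radius_um = c(5, 6, 5),
    amplitude = 1000, sigma_um = 1.2,
    attenuation = c(0.58, 0.58, 1.0),
    quantifiable = TRUE,
    stringsAsFactors = FALSE)
}

small_config <- function(...) {
  brain_config(cluster_spec = small_cluster_spec(), hemispheres = "L",
               image_shape = c(24L, 80L, 80L), ...)
}

# one isolated neuron, used for analytic-oracle tests
single_neuron_spec <- function(amplitude = 1000, sigma_um = 1.2) {
  data.frame(cluster = "PAL", count = 1L, x = 30, y = 30, z = 12,
             radius_um = 1e-6, amplitude = amplitude, sigma_um = sigma_um,
             attenuation = 1.0, quantifiable = TRUE,
             stringsAsFactors = FALSE)
}

# independent pixel-in-polygon oracle: winding-angle accumulation, scalar
# arithmetic - a different formulation from the package's ray-crossing rule
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  ang <- 0
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    ax <- poly[k, 1] - px;  ay <- poly[k, 2] - py
    bx <- poly[k2, 1] - px; by <- poly[k2, 2] - py
    ang <- ang + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  abs(ang) > pi
}

# random star-shaped polygon (always simple; angular gaps kept well away
# from zero so vertex order is unambiguous)
random_star_polygon <- function(n_vertices, cx, cy, r_min, r_max) {
  gaps <- runif(n_vertices, 0.15, 1)
  th <- 2 * pi * cumsum(gaps) / sum(gaps)
  r <- runif(n_vertices, r_min, r_max)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}
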