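test_that("ROI slice measurement matches the worked square example", {
  vox <- array(10, c(1, 8, 8))
  st <- zstack(vox, pixel_size_um = 0.5)
  # axis-aligned square strictly enclosing the 9 pixel centers (2..4)^2
  roi <- roi_contour("n1", "PAL", "L",
                     rbind(c(1.5, 1.5), c(4.5, 1.5), c(4.5, 4.5),
                           c(1.5, 4.5)),
                     z_first = 0, z_last = 0)
  m <- measure_roi_slice(st, roi, 0)
  expect_equal(m$area_px, 9)
  expect_equal(m$intensity_sum, 90)
  expect_equal(m$intensity_mean, 10)
  expect_equal(m$area_um2, 9 * 0.25)
})

test_that("polygon validation rejects degenerate and crossing contours", {
  expect_error(roi_contour("n", "PAL", "L", rbind(c(0, 0), c(1, 1)), 0, 0),
               ">= 3")
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(roi_contour("n", "PAL", "L", bowtie, 0, 0), "simple")
  expect_error(roi_contour("n", "BAD", "L", diag(3)[, 1:2], 0, 0),
               "unknown cluster")
  expect_error(roi_contour("n", "PAL", "M", rbind(c(0, 0), c(3, 0),
                                                  c(0, 3)), 0, 0),
               "hemisphere")
})

test_that("an ROI holding no pixel centers errors", {
  st <- zstack(array(1, c(1, 10, 10)), 1)
  tiny <- roi_contour("n", "PAL", "L",
                      rbind(c(3.1, 3.1), c(3.4, 3.1), c(3.25, 3.4)), 0, 0)
  expect_error(measure_roi_slice(st, tiny, 0), "empty ROI")
})

test_that("measurement equals the exhaustive pixel-center oracle", {
  # 200 random polygon/image pairs compared against an independently
  # formulated (winding-angle) membership oracle
  set.seed(101)
  for (case in 1:200) {
    st <- zstack(array(runif(16 * 16, 0, 1000), c(1, 16, 16)), 1)
    poly <- if (case %% 2 == 0) {
      random_star_polygon(sample(3:12, 1), runif(1, 4, 11),
                          runif(1, 4, 11), 1.2, 4.5)
    } else {
      random_star_polygon(3, runif(1, 4, 11), runif(1, 4, 11), 1.5, 5)
    }
    grid <- expand.grid(x = 0:15, y = 0:15)
    want <- mapply(oracle_point_in_polygon, grid$x, grid$y,
                   MoreArgs = list(poly = poly))
    if (!any(want)) next
    roi <- roi_contour(paste0("c", case), "PPL1", "L", poly, 0, 0)
    m <- measure_roi_slice(st, roi, 0)
    expect_equal(m$area_px, sum(want))
    expect_equal(m$intensity_sum,
                 sum(st$voxels[1, , ][cbind(grid$y[want] + 1,
                                            grid$x[want] + 1)]))
  }
})

test_that("measure_neuron accumulates the z-window", {
  st <- zstack(array(7, c(12, 20, 20)), 0.5)
  roi <- roi_contour("n", "PPM3", "L", circle_polygon(10, 10, 4),
                     z_first = 0, z_last = 10)
  m <- measure_neuron(st, roi)
  expect_s3_class(m, "neuron_measurement")
  expect_equal(m$n_slices, 11)
  a <- m$slices$area_px[1]
  expect_equal(m$neuron_fi, 11 * a * 7)
  expect_equal(nrow(m$slices), 11)
  # per-slice mean * area == sum
  expect_equal(m$slices$intensity_mean * m$slices$area_px,
               m$slices$intensity_sum)

  bad <- roi_contour("n", "PPM3", "L", circle_polygon(10, 10, 4), 5, 14)
  expect_error(measure_neuron(st, bad), "exceeds stack depth")
})

test_that("per-slice polygons are honoured", {
  st <- zstack(array(1, c(3, 12, 12)), 1)
  roi <- roi_contour("n", "PAL", "L", circle_polygon(5, 5, 3), 0, 2)
  polys <- list(circle_polygon(5, 5, 3), circle_polygon(5, 5, 1.2),
                circle_polygon(5, 5, 3))
  m <- measure_neuron(st, roi, polygons = polys)
  expect_lt(m$slices$area_px[2], m$slices$area_px[1])
})

test_that("a synthetic Gaussian neuron is recovered within 5% of truth", {
  cfg <- brain_config(cluster_spec = single_neuron_spec(),
                      hemispheres = "L", image_shape = c(24L, 64L, 64L),
                      background_level = 0, noise_sd = 0,
                      min_sep_um = 0, z_jitter_slices = 0,
                      roi_sigma_mult = 3)  # generous contour
  gb <- generate_brain(cfg, "control", seed = 5)
  m <- measure_neuron(gb$stack, gb$rois[[1]])
  # truth restricted to the 11-slice window (discrete slice sum)
  sz <- 1.2 / 1.08
  zc <- gb$truth$z[1]
  zw <- gb$rois[[1]]$z_first:gb$rois[[1]]$z_last
  frac_z <- sum(exp(-(zw - zc)^2 / (2 * sz^2))) /
    sum(exp(-((-50:73) - zc)^2 / (2 * sz^2)))
  expect_equal(m$neuron_fi, gb$truth$true_fi[1] * frac_z,
               tolerance = 0.05)
})

test_that("brain summaries add up and are order-invariant", {
  mk <- function(id, cl, fi) {
    structure(list(neuron_id = id, cluster = cl, hemisphere = "L",
                   slices = NULL, neuron_fi = fi, n_slices = 11L),
              class = "neuron_measurement")
  }
  ms <- list(mk("a", "PAL", 5), mk("b", "PAL", 7), mk("c", "PPL2", 3))
  s <- summarize_brain(ms, "b1", "control")
  expect_equal(s$clusters$cluster_fi[s$clusters$cluster == "PAL"], 12)
  expect_equal(s$total_fi, 15)
  expect_equal(s$total_neurons, 3)
  s2 <- summarize_brain(rev(ms), "b1", "control")
  expect_equal(s2$total_fi, s$total_fi)
  expect_equal(s2$clusters, s$clusters)

  empty <- summarize_brain(list(), "b0", "control")
  expect_equal(empty$total_fi, 0)
  expect_equal(empty$total_neurons, 0)
})

test_that("intensity scaling propagates exactly through all sums", {
  cfg <- small_config(noise_sd = 0)
  gb <- generate_brain(cfg, "control", seed = 3)
  s1 <- quantify_brain(gb$stack, gb$rois)
  st2 <- gb$stack
  st2$voxels <- st2$voxels * 3.7
  s2 <- quantify_brain(st2, gb$rois)
  expect_equal(s2$total_fi, 3.7 * s1$total_fi)
  expect_equal(s2$clusters$cluster_fi, 3.7 * s1$clusters$cluster_fi)
})
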