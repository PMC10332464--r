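test_that("default atlas carries the stated census", {
  cs <- default_cluster_spec()
  q <- cs$quantifiable
  expect_equal(sum(cs$count[q]), 40)
  expect_equal(sum(cs$count[cs$cluster %in% c(QUANTIFIABLE_CLUSTERS,
                                              "PAM")]), 140)
  expect_equal(cs$count[cs$cluster == "PAM"], 100)
  expect_equal(cs$attenuation[cs$cluster == "PPM1/2"], 1.0)
  expect_equal(unique(cs$attenuation[cs$cluster %in%
                                       c("PAL", "PPL1", "PPL2", "PPM3")]),
               0.58)
})

test_that("generated ground truth matches the configured census", {
  gb <- generate_brain(brain_config(hemispheres = "L"), "control",
                       seed = 42)
  expect_equal(nrow(gb$truth), 140)
  expect_equal(sum(gb$truth$quantifiable), 40)
  expect_equal(sum(gb$truth$cluster == "PAM"), 100)
  expect_equal(length(gb$rois), 40)
  # both hemispheres double everything
  gb2 <- generate_brain(brain_config(), "control", seed = 42)
  expect_equal(nrow(gb2$truth), 280)
  expect_equal(table(gb2$truth$hemisphere)[["L"]], 140)
})

test_that("treated condition preserves positions and attenuates truth FI", {
  cfg <- small_config()
  gc <- generate_brain(cfg, "control", seed = 11)
  gt <- generate_brain(cfg, "treated", seed = 11)
  expect_identical(gc$truth[, c("id", "cluster", "x", "y", "z")],
                   gt$truth[, c("id", "cluster", "x", "y", "z")])
  expect_true(all(gt$truth$true_fi <= gc$truth$true_fi))
  att <- ifelse(gc$truth$cluster == "PPM3", 1.0, 0.58)
  expect_equal(gt$truth$true_fi, gc$truth$true_fi * att)
})

test_that("unit attenuation and zero noise give voxel-identical stacks", {
  cs <- small_cluster_spec()
  cs$attenuation <- 1.0
  cfg <- brain_config(cluster_spec = cs, hemispheres = "L",
                      image_shape = c(24L, 80L, 80L), noise_sd = 0)
  gc <- generate_brain(cfg, "control", seed = 4)
  gt <- generate_brain(cfg, "treated", seed = 4)
  expect_identical(gc$stack$voxels, gt$stack$voxels)
})

test_that("default attenuation yields the closed-form 32.55% FI reduction", {
  cfg <- brain_config(noise_sd = 0)
  gc <- generate_brain(cfg, "control", seed = 9)
  gt <- generate_brain(cfg, "treated", seed = 9)
  red <- (attr(gc$truth, "total_true_fi") - attr(gt$truth, "total_true_fi")) /
    attr(gc$truth, "total_true_fi") * 100
  expect_equal(red, 31 * 0.42 / 40 * 100, tolerance = 1e-10)
  expect_equal(red, 32.55, tolerance = 0.1 / 32.55)
})

test_that("true treated/control FI ratio equals count-weighted attenuation", {
  cfg <- small_config()
  gc <- generate_brain(cfg, "control", seed = 21)
  gt <- generate_brain(cfg, "treated", seed = 21)
  cs <- small_cluster_spec()
  expected <- sum(cs$count * cs$attenuation) / sum(cs$count)
  expect_equal(attr(gt$truth, "total_true_fi") /
                 attr(gc$truth, "total_true_fi"), expected)
})

test_that("generation is bit-reproducible and leaves the RNG untouched", {
  cfg <- small_config()
  set.seed(999)
  before <- .Random.seed
  g1 <- generate_brain(cfg, "control", seed = 6)
  expect_identical(.Random.seed, before)
  g2 <- generate_brain(cfg, "control", seed = 6)
  expect_identical(g1$stack$voxels, g2$stack$voxels)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_brain(cfg, "control", seed = 7)
  expect_false(identical(g1$stack$voxels, g3$stack$voxels))
})

test_that("configs whose blobs leave the image are rejected", {
  cs <- small_cluster_spec()
  cs$x[1] <- 2  # support crosses the x = 0 edge
  expect_error(brain_config(cluster_spec = cs, hemispheres = "L",
                            image_shape = c(24L, 80L, 80L)),
               "outside the image")
  cs2 <- small_cluster_spec()
  cs2$z <- 2
  expect_error(brain_config(cluster_spec = cs2, hemispheres = "L",
                            image_shape = c(24L, 80L, 80L)), "stack|z-window")
  expect_error(brain_config(cluster_spec = within(small_cluster_spec(),
                                                  amplitude <- -1)),
               "amplitude")
  expect_error(brain_config(cluster_spec = within(small_cluster_spec(),
                                                  attenuation <- 1.2)),
               "attenuation")
})

test_that("generated stacks respect the intensity floor", {
  gb <- generate_brain(small_config(background_level = 0, noise_sd = 30),
                       "control", seed = 2)
  expect_true(all(gb$stack$voxels >= 0))
})
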