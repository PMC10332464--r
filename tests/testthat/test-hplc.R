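test_that("triangular and Gaussian peak areas match closed forms", {
  # isoceles triangle, base 1 min, height 10, zero baseline
  t <- seq(0, 5, by = 1 / 300)
  y <- pmax(0, 10 * (1 - abs(t - 2.5) / 0.5))
  peaks <- detect_and_integrate(chromatogram(t, y), min_height = 1,
                                min_prominence = 0.5)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$area, 10 * 1 / 2, tolerance = 0.005)

  # Gaussian amplitude A, sigma s: area = A s sqrt(2 pi)
  A <- 40; s <- 0.1
  y2 <- A * exp(-(t - 2)^2 / (2 * s^2))
  p2 <- detect_and_integrate(chromatogram(t, y2), min_height = 1,
                             min_prominence = 0.5)
  expect_equal(p2$area, A * s * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(p2$apex_time, 2, tolerance = 0.01)
})

test_that("disjoint peaks integrate additively and in apex order", {
  t <- seq(0, 12, by = 1 / 300)
  y <- 30 * exp(-(t - 3)^2 / (2 * 0.08^2)) +
    50 * exp(-(t - 8)^2 / (2 * 0.08^2))
  peaks <- detect_and_integrate(chromatogram(t, y), min_height = 5,
                                min_prominence = 1)
  expect_equal(nrow(peaks), 2)
  expect_true(all(diff(peaks$apex_time) > 0))
  one <- detect_and_integrate(
    chromatogram(t, 30 * exp(-(t - 3)^2 / (2 * 0.08^2))), 5, 1)
  two <- detect_and_integrate(
    chromatogram(t, 50 * exp(-(t - 8)^2 / (2 * 0.08^2))), 5, 1)
  expect_equal(sum(peaks$area), one$area + two$area, tolerance = 0.01)
})

test_that("flat or invalid chromatograms are handled", {
  t <- seq(0, 2, by = 0.01)
  expect_equal(nrow(detect_and_integrate(chromatogram(t, rep(3, length(t))),
                                         1, 0.5)), 0)
  expect_error(detect_and_integrate(chromatogram(0:5 / 10, rep(1, 6))),
               "too short")
  expect_error(chromatogram(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(chromatogram(1:3, 1:2), "equal length")
})

test_that("the generator's peaks carry the requested areas", {
  rt <- default_retention_times()
  cfg <- chrom_config(noise_sd = 0, baseline = 0, drift_per_min = 0)
  ch <- generate_chromatogram(c(DOPAC = 40, DA = 120, HVA = 25), rt, cfg)
  peaks <- detect_and_integrate(ch, min_height = 5, min_prominence = 1)
  lab <- identify_peaks(peaks, rt)
  expect_setequal(lab$analyte, c("DOPAC", "DA", "HVA"))
  for (a in names(rt)) {
    expect_equal(lab$area[lab$analyte == a],
                 c(DOPAC = 40, DA = 120, HVA = 25)[[a]],
                 tolerance = 0.02)
  }
  # all concentrations zero -> flat baseline
  flat <- generate_chromatogram(c(DA = 0), rt, cfg)
  expect_equal(unique(round(flat$signal, 10)), 0)
  # overlapping peaks are flagged
  expect_warning(
    over <- generate_chromatogram(c(DOPAC = 10, DA = 10),
                                  c(DOPAC = 3.5, DA = 3.6), cfg),
    "4 sigma")
  expect_true(attr(over, "overlap_warning"))
})

test_that("retention-time identification applies tolerance and ties", {
  peaks <- data.frame(analyte = NA_character_,
                      apex_time = c(3.5, 5.6, 9.9), area = 1:3)
  std <- c(DOPAC = 3.5, DA = 5.0, HVA = 8.0)
  lab <- identify_peaks(peaks, std, tolerance_min = 0.2)
  expect_equal(lab$analyte, c("DOPAC", NA, NA))
  # equidistant tie breaks toward the earlier-eluting standard
  lab2 <- identify_peaks(data.frame(analyte = NA, apex_time = 4.25,
                                    area = 1),
                         c(DOPAC = 4.0, DA = 4.5), tolerance_min = 0.5)
  expect_equal(lab2$analyte, "DOPAC")
})

test_that("spiking confirms true analytes and rejects unspiked runs", {
  rt <- default_retention_times()
  cfg <- chrom_config(noise_sd = 0)
  samp_amt <- c(DOPAC = 40, DA = 120, HVA = 25)
  samp <- generate_chromatogram(samp_amt, rt, cfg)
  spiked <- generate_chromatogram(samp_amt + 100, rt, cfg)
  conf <- confirm_by_spiking(samp, spiked, rt, min_height = 5,
                             min_prominence = 1)
  expect_true(all(conf$verdict == "confirmed"))

  same <- confirm_by_spiking(samp, samp, rt, min_height = 5,
                             min_prominence = 1)
  expect_true(all(same$verdict == "not confirmed"))

  # a label whose peak never appears
  rt4 <- c(rt, HIAA = 10.5)
  conf4 <- confirm_by_spiking(samp, spiked, rt4, min_height = 5,
                              min_prominence = 1)
  expect_equal(conf4$verdict[conf4$analyte == "HIAA"], "not found")
})

test_that("end-to-end amount recovery stays within 3% at default noise", {
  rt <- default_retention_times()
  std <- generate_chromatogram(c(DOPAC = 100, DA = 100, HVA = 100), rt,
                               seed = 51)
  smp <- generate_chromatogram(c(DOPAC = 40, DA = 120, HVA = 25), rt,
                               seed = 52)
  sp <- identify_peaks(detect_and_integrate(std, 1, 0.5), rt)
  mp <- identify_peaks(detect_and_integrate(smp, 1, 0.5), rt)
  q <- quantify_catecholamine(
    C_Std = 200, A_Std = sp$area[sp$analyte == "DA"], I_Std = 20,
    A_Samp = mp$area[mp$analyte == "DA"], I_Samp = 50, N = 15,
    P_Samp = 1.0)
  # generator truth: amounts are areas, so V2 = 4 ng * 120/100
  expect_equal(q$V2, 4 * 120 / 100, tolerance = 0.03)
})
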