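test_that("perfect copying with no jitter yields a fully aligned field", {
  f <- generateSigmaField(8, 8, p_align = 1, jitter_sd = 0, seed = 3)
  p <- adjacentPairs(f)
  expect_equal(nrow(p), 3 * 64 - 2 * 8 - 2 * 8 + 1)
  expect_true(all(p$delta_sigma_deg < 1e-9))
})

test_that("independent axes give uniform adjacent axial differences", {
  f <- generateSigmaField(60, 60, p_align = 0, seed = 4)
  d <- adjacentPairs(f)$delta_sigma_deg
  expect_gt(length(d), 1e4)
  expect_equal(mean(d), 22.5, tolerance = 0.03)
  ## Kolmogorov-Smirnov distance to Uniform[0, 45]
  ks <- max(abs(stats::ecdf(d)(seq(0, 45, by = 0.25)) -
    seq(0, 45, by = 0.25) / 45))
  expect_lt(ks, 0.03)
})

test_that("calibrated ensemble reproduces the observed misalignment fractions", {
  f <- generateSigmaField(60, 60, mixture = "calibrated", seed = 11)
  d <- adjacentPairs(f)$delta_sigma_deg
  expect_gt(length(d), 2000)
  ## absolute bands of about four sampling standard deviations at this
  ## lattice size (adjacent pairs share cells, inflating binomial error)
  expect_lt(abs(mean(d < 1e-9) - 0.22), 0.04)
  expect_lt(abs(mean(d <= 5) - 0.50), 0.05)
  expect_lt(abs(mean(d >= 15) - 0.30), 0.045)
  expect_lt(abs(mean(d >= 20) - 0.15), 0.03)
})

test_that("field generation is seeded, bounded and validated", {
  f1 <- generateSigmaField(10, 10, seed = 7)
  f2 <- generateSigmaField(10, 10, seed = 7)
  f3 <- generateSigmaField(10, 10, seed = 8)
  expect_identical(sigmaValues(f1), sigmaValues(f2))
  expect_false(identical(sigmaValues(f1), sigmaValues(f3)))
  expect_true(all(sigmaValues(f1) >= 0 & sigmaValues(f1) < 90))
  expect_true(all(isMeasured(f1)))
  g1 <- generateSigmaField(20, 20, mixture = "calibrated", seed = 9)
  g2 <- generateSigmaField(20, 20, mixture = "calibrated", seed = 9)
  expect_identical(sigmaValues(g1), sigmaValues(g2))
  expect_error(generateSigmaField(5, 5, p_align = 1.2), "p_align")
  expect_error(generateSigmaField(5, 5, jitter_sd = -1), "jitter_sd")
  bad <- calibratedMixtureParams(); bad$p_exact <- 0.9
  expect_error(generateSigmaField(5, 5, mixture = bad), "sum to 1")
})

test_that("polarization image pairs have the requested DoP", {
  p0 <- generatePolarizationImagePair(0, noise_sd = 0)
  expect_identical(p0$i_h, p0$i_v)
  p1 <- generatePolarizationImagePair(1, noise_sd = 0)
  expect_true(all(p1$i_v == 0))
  p5 <- generatePolarizationImagePair(0.5, noise_sd = 0)
  expect_equal(imagePairDop(p5$i_h, p5$i_v)$dop, 0.5)
  expect_equal(mean(p5$i_h) + mean(p5$i_v), 200)
  expect_error(generatePolarizationImagePair(1.2), "dop")
  a <- generatePolarizationImagePair(0.3, noise_sd = 2, seed = 5)
  b <- generatePolarizationImagePair(0.3, noise_sd = 2, seed = 5)
  expect_identical(a, b)
})

test_that("reflectance templates peak where requested", {
  fem <- forewingTemplate("female")
  mal <- forewingTemplate("male")
  expect_equal(fem$wavelength_nm[which.max(fem$reflectance)], 521)
  expect_equal(mal$wavelength_nm[which.max(mal$reflectance)], 545)
  ## peak position is invariant to amplitude scaling
  dbl <- generateReflectanceSpectrum(521, amplitude = 0.7)
  expect_equal(dbl$wavelength_nm[which.max(dbl$reflectance)], 521)
  expect_error(generateReflectanceSpectrum(521, step_nm = 0), "step")
  expect_error(generateReflectanceSpectrum(800), "inside range")
})

test_that("sensitivity templates are unit-peak Gaussians of the right mass", {
  s <- generateSensitivityTemplates(range_nm = c(200, 1000))
  for (k in c("u", "s", "m", "l")) expect_equal(max(s[[k]]), 1)
  expect_equal(s$u[s$wavelength_nm == 360], 1)
  expect_lt(s$u[s$wavelength_nm == 700], 1e-6)
  ## Gaussian integral: fwhm * sqrt(pi / ln 16)
  expected <- 80 * sqrt(pi / log(16))
  for (k in c("u", "s", "m", "l"))
    expect_equal(sum(s[[k]]), expected, tolerance = 0.01)
  expect_error(generateSensitivityTemplates(peaks_nm = c(360, 360, 520, 600)),
    "distinct")
})

test_that("behavioural counts are seeded binomials with the right mean", {
  t1 <- generateBehaviorCounts(seed = 2)
  t2 <- generateBehaviorCounts(seed = 2)
  expect_identical(t1, t2)
  expect_equal(sum(t1$n_polarized + t1$n_depolarized), 183)
  ## across seeds the mean depolarized total matches 113 of 183
  tot <- vapply(1:200, function(s)
    sum(generateBehaviorCounts(seed = s)$n_depolarized), numeric(1))
  expect_equal(mean(tot), 113, tolerance = 0.02)
  ## p = 1/2 balances the expected per-site difference
  d <- vapply(1:200, function(s) {
    tab <- generateBehaviorCounts(p_depol = 0.5, seed = s)
    mean(tab$n_polarized - tab$n_depolarized)
  }, numeric(1))
  expect_lt(abs(mean(d)), 1)
  expect_error(generateBehaviorCounts(p_depol = 2), "p_depol")
})
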