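test_that("DoP of channel totals follows the printed definition", {
  expect_equal(computeDop(1, 1), 0)
  expect_equal(computeDop(2, 1), 1 / 3)
  expect_equal(computeDop(1, 0), 1)
  expect_equal(computeDop(1, 2), 1 / 3)  # unsigned
  expect_error(computeDop(0, 0), "zero")
  expect_error(computeDop(-1, 2), "non-negative")
})

test_that("image-pair DoP round-trips the generator and scales out", {
  p <- generatePolarizationImagePair(0.5, noise_sd = 0)
  r <- imagePairDop(p$i_h, p$i_v)
  expect_equal(r$dop, 0.5)
  expect_equal(r$dominant, "H")
  expect_equal(imagePairDop(p$i_v, p$i_h)$dominant, "V")
  expect_equal(imagePairDop(7 * p$i_h, 7 * p$i_v)$dop, 0.5)
  expect_error(imagePairDop(p$i_h, p$i_v[1:10, 1:10]), "shape")
  expect_error(
    imagePairDop(p$i_h, p$i_v, mask = matrix(FALSE, 64, 64)),
    "mask")
  ## masking restricts the totals to the selected pixels
  m <- matrix(FALSE, 64, 64); m[1:8, 1:8] <- TRUE
  ih <- p$i_h; ih[!m] <- 1e6
  expect_equal(imagePairDop(ih, p$i_v, mask = m)$dop, 0.5)
})

test_that("noisy DoP estimates fall within propagated standard errors", {
  truth <- 0.4; noise <- 5; npix <- 64 * 64
  hits <- 0
  for (s in 1:100) {
    p <- generatePolarizationImagePair(truth, total_intensity = 200,
      noise_sd = noise, seed = s)
    r <- imagePairDop(p$i_h, p$i_v)
    th <- r$i_h_total; tv <- r$i_v_total
    se <- sqrt((2 * tv)^2 + (2 * th)^2) * noise * sqrt(npix) / (th + tv)^2
    if (abs(r$dop - truth) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("DoP sweeps check geometry and enumerate the acquisition grid", {
  mk <- function(theta, phi, dop = 0.3, contrast = NULL) {
    p <- generatePolarizationImagePair(dop, shape = c(8, 8), noise_sd = 0)
    list(i_h = p$i_h, i_v = p$i_v, theta_inc = theta, phi_det = phi,
      angular_contrast = contrast)
  }
  sw <- dopSweep(list(mk(60, 60), mk(0, 10)))
  expect_equal(sw$angular_contrast, c(120, 10))
  expect_equal(sw$dop, c(0.3, 0.3))
  expect_error(dopSweep(list(mk(60, 60, contrast = 100))), "inconsistent")
  expect_error(dopSweep(list()), "at least one")
  ## full acquisition grid with |theta| < phi: combinatorial oracle
  combos <- list(); n_oracle <- 0
  for (th in seq(-60, 70, by = 10)) for (ph in seq(10, 70, by = 10)) {
    if (abs(th) < ph) {
      n_oracle <- n_oracle + 1
      combos[[n_oracle]] <- mk(th, ph)
    }
  }
  expect_equal(nrow(dopSweep(combos)), n_oracle)
})

test_that("polynomial trends recover their generating polynomials", {
  x <- seq(20, 140, by = 10)
  quad <- data.frame(angular_contrast = x,
    dop = 0.1 + 0.004 * x - 1.5e-5 * x^2)
  f2 <- fitDopTrend(quad, order = 2)
  expect_lt(f2$residual_sd, 1e-12)
  expect_equal(unname(stats::predict(f2$model)), quad$dop,
    tolerance = 1e-9)
  ## cubic truth: the cubic fit dominates the quadratic one
  cub <- data.frame(angular_contrast = x,
    dop = 0.1 + 1e-6 * (x - 70)^3 + 0.002 * x)
  expect_lt(fitDopTrend(cub, 3)$residual_sd,
    fitDopTrend(cub, 2)$residual_sd)
  ## constant response: higher-order coefficients vanish
  const <- data.frame(angular_contrast = x, dop = 0.25)
  f0 <- fitDopTrend(const, 2)
  expect_equal(unname(f0$coefficients[-1]), c(0, 0), tolerance = 1e-12)
  expect_error(fitDopTrend(quad[1:3, ], 2), "at least")
  expect_error(
    fitDopTrend(data.frame(angular_contrast = rep(50, 8), dop = 1:8 / 10), 2),
    "rank")
})

test_that("spectral peaks flag ties and boundary maxima", {
  expect_equal(spectralPeak(forewingTemplate("female"))$peak_nm, 521)
  expect_equal(spectralPeak(forewingTemplate("male"))$peak_nm, 545)
  ramp <- data.frame(wavelength_nm = 350:700,
    reflectance = seq(0, 1, length.out = 351))
  pr <- spectralPeak(ramp)
  expect_true(pr$boundary)
  expect_equal(pr$peak_nm, 700)
  twin <- data.frame(wavelength_nm = 1:5, reflectance = c(0, 1, 0, 1, 0))
  pt <- spectralPeak(twin)
  expect_true(pt$tie)
  expect_equal(pt$peak_nm, 2)
  expect_error(
    spectralPeak(data.frame(wavelength_nm = 1:5, reflectance = rep(1, 5))),
    "constant")
})

test_that("quantum catches integrate reflectance against the sensitivities", {
  ## flat reflectance, symmetric well-separated curves: equal catches
  sens <- generateSensitivityTemplates(peaks_nm = c(400, 500, 600, 700),
    fwhm_nm = 60, range_nm = c(200, 1000))
  flat <- data.frame(wavelength_nm = 200:1000, reflectance = 0.5)
  qc <- quantumCatches(flat, sens, range_nm = c(200, 1000))
  expect_equal(unname(qc$relative), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(unname(qc$xyz), c(0, 0, 0), tolerance = 1e-9)
  ## reflectance equal to one curve, others non-overlapping: it dominates
  nar <- generateSensitivityTemplates(peaks_nm = c(360, 450, 540, 630),
    fwhm_nm = 20, range_nm = c(300, 800))
  ref_u <- data.frame(wavelength_nm = nar$wavelength_nm, reflectance = nar$u)
  qcu <- quantumCatches(ref_u, nar, range_nm = c(300, 800))
  expect_gt(qcu$relative[["u"]], 0.99)
  ## analytic Gaussian x Gaussian overlap
  s <- 60 / (2 * sqrt(2 * log(2)))
  spec <- generateReflectanceSpectrum(520, fwhm_nm = 60, amplitude = 1,
    pedestal = 0, range_nm = c(200, 1000))
  qg <- quantumCatches(spec, sens, range_nm = c(200, 1000))
  analytic <- sqrt(pi) * s *
    exp(-(c(400, 500, 600, 700) - 520)^2 / (4 * s^2))
  expect_equal(unname(qg$catch), analytic, tolerance = 0.005)
  expect_error(
    quantumCatches(data.frame(wavelength_nm = 350:700, reflectance = 0),
      sens),
    "zero")
})

test_that("the tetrahedral map places vertices regularly around the origin", {
  expect_equal(unname(tetraCoordinates(c(0.25, 0.25, 0.25, 0.25))),
    c(0, 0, 0))
  verts <- diag(4)
  xyz <- apply(verts, 1, tetraCoordinates)
  expect_equal(unname(xyz[, 1]), c(0, 0, 0.75))  # pure u at the apex
  ## every vertex at distance 0.75 from the achromatic centre
  expect_equal(unname(sqrt(colSums(xyz^2))), rep(0.75, 4))
  ## regular: all six inter-vertex distances equal
  dd <- as.vector(stats::dist(t(xyz)))
  expect_equal(dd, rep(dd[1], 6))
  expect_error(tetraCoordinates(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("colour distances are a metric on tetrahedral coordinates", {
  set.seed(33)
  for (i in 1:25) {
    raw <- matrix(runif(12), 3, 4)
    rel <- raw / rowSums(raw)
    a <- tetraCoordinates(rel[1, ]); b <- tetraCoordinates(rel[2, ])
    cc <- tetraCoordinates(rel[3, ])
    expect_equal(colorDistance(a, b), colorDistance(b, a))
    expect_equal(colorDistance(a, a), 0)
    expect_lte(colorDistance(a, cc),
      colorDistance(a, b) + colorDistance(b, cc) + 1e-12)
  }
  ## flat scaling of reflectance leaves relative catches and colours fixed
  sens <- generateSensitivityTemplates()
  sp <- forewingTemplate("female")
  sp2 <- sp; sp2$reflectance <- 3 * sp2$reflectance
  expect_equal(quantumCatches(sp, sens)$xyz, quantumCatches(sp2, sens)$xyz)
})
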