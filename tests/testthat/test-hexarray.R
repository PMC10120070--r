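test_that("axial neighbourhoods match the lattice geometry", {
  f <- generateSigmaField(5, 5, seed = 1)
  expect_equal(nrow(measuredNeighbors(f, 2, 2)), 6)
  expect_equal(nrow(measuredNeighbors(f, 0, 0)), 2)  # rhombus corner
  expect_equal(nrow(measuredNeighbors(f, 4, 0)), 3)  # opposite corner
  ## geometric oracle: neighbours are the cells one spacing away
  for (cell in list(c(2, 2), c(0, 3), c(4, 4))) {
    got <- measuredNeighbors(f, cell[1], cell[2])
    cc <- latticeCoords(f)
    pos <- hexAxialToPixel(cc$q, cc$r, 20)
    me <- hexAxialToPixel(cell[1], cell[2], 20)
    d <- sqrt((pos$x - me$x)^2 + (pos$y - me$y)^2)
    want <- cc[d > 1e-9 & d < 20 * 1.01, ]
    expect_setequal(paste(got$q, got$r), paste(want$q, want$r))
  }
})

test_that("interior ommatidia are those with six measured neighbours", {
  f1 <- SigmaField(q = 0, r = 0, sigma = 10)
  expect_equal(nrow(interiorOmmatidia(f1)), 0)
  f <- generateSigmaField(5, 5, seed = 2)
  int <- interiorOmmatidia(f)
  oracle <- bruteInterior(f)
  expect_setequal(paste(int$q, int$r), paste(oracle$q, oracle$r))
  expect_equal(nrow(int), 9)  # 3 x 3 core of the 5 x 5 rhombus
  ## removing a neighbour demotes an interior cell
  g <- f
  cc <- latticeCoords(g)
  isMeasured(g)[cc$q == 2 & cc$r == 1] <- FALSE
  int2 <- interiorOmmatidia(g)
  expect_false(any(int2$q == 2 & int2$r == 2))
  expect_setequal(paste(int2$q, int2$r),
    paste(bruteInterior(g)$q, bruteInterior(g)$r))
})

test_that("adjacent pairs are counted once with correct classification", {
  f2 <- SigmaField(q = c(0, 1), r = c(0, 0), sigma = c(10, 40))
  p <- adjacentPairs(f2)
  expect_equal(nrow(p), 1)
  expect_equal(p$delta_sigma_deg, 30)
  expect_true(p$is_pd)
  ## rhombic lattice edge-count formula 3nm - 2n - 2m + 1
  for (dims in list(c(5, 5), c(8, 4), c(12, 3))) {
    f <- generateSigmaField(dims[1], dims[2], seed = sum(dims))
    n <- dims[1]; m <- dims[2]
    expect_equal(nrow(adjacentPairs(f)), 3 * n * m - 2 * n - 2 * m + 1)
  }
  expect_error(adjacentPairs(SigmaField(0, 0, 10)), "at least two")
})

test_that("interior restriction keeps pairs touching the interior set", {
  f <- generateSigmaField(6, 6, seed = 3)
  all_p <- adjacentPairs(f)
  int_p <- adjacentPairs(f, restrict_interior = TRUE)
  expect_lt(nrow(int_p), nrow(all_p))
  ikey <- with(interiorOmmatidia(f), paste(q, r))
  expect_true(all(
    paste(int_p$a_q, int_p$a_r) %in% ikey |
      paste(int_p$b_q, int_p$b_r) %in% ikey))
})

test_that("edge-detector chains respect the alignment band", {
  ## a row of four equal axes: exactly one chain of length four
  f <- SigmaField(q = 0:3, r = rep(0L, 4), sigma = rep(30, 4))
  ch <- findEdChains(f)
  expect_equal(length(unique(ch$chain_id)), 1)
  expect_equal(max(ch$n), 4)
  expect_equal(unique(ch$spread_deg), 0)
  ## (0, 11, 0): pairwise difference 11 exceeds the 10-degree band
  f2 <- SigmaField(q = 0:2, r = rep(0L, 3), sigma = c(0, 11, 0))
  expect_equal(nrow(findEdChains(f2)), 0)
  ## (0, 5, 10): max pairwise difference equals the band edge, qualifies
  f3 <- SigmaField(q = 0:2, r = rep(0L, 3), sigma = c(0, 5, 10))
  ch3 <- findEdChains(f3)
  expect_equal(length(unique(ch3$chain_id)), 1)
  expect_equal(unique(ch3$spread_deg), 10)
})

test_that("chain finding agrees with an exhaustive window scan", {
  set.seed(42)
  cases <- list(
    generateSigmaField(6, 6, p_align = 0.9, jitter_sd = 2, seed = 31),
    generateSigmaField(9, 7, p_align = 0.6, jitter_sd = 4, seed = 32),
    generateSigmaField(12, 12, p_align = 0.85, jitter_sd = 3, seed = 33),
    generateSigmaField(12, 5, mixture = "calibrated", seed = 34)
  )
  for (f in cases) {
    expect_identical(encodeChains(findEdChains(f)), bruteChains(f))
    ## tighter and looser tolerances than the default
    expect_identical(encodeChains(findEdChains(f, ed_tol = 2)),
      bruteChains(f, ed_tol = 2))
    expect_identical(encodeChains(findEdChains(f, ed_tol = 10, min_len = 4)),
      bruteChains(f, ed_tol = 10, min_len = 4))
  }
  ## unmeasured cells break runs
  f <- generateSigmaField(8, 8, p_align = 1, jitter_sd = 0, seed = 35)
  isMeasured(f)[20] <- FALSE
  expect_identical(encodeChains(findEdChains(f)), bruteChains(f))
})

test_that("patch metrics capture fully aligned and fully misaligned designs", {
  al <- generateSigmaField(6, 6, p_align = 1, jitter_sd = 0, seed = 4)
  m <- patchMetrics(al)
  expect_equal(m$n_interior, 16)
  expect_equal(m$pct_ed, 100)
  expect_equal(m$pct_pd, 0)
  expect_equal(m$pct_ed_only, 100)
  expect_equal(m$delta_sigma_summary$exact, 1)
  ## three-phase pattern {0, 30, 60}: every adjacent pair differs by 30,
  ## every collinear triple spans 60 - all PD, no ED
  tp <- threePhaseField(6, 6)
  expect_true(all(adjacentPairs(tp)$delta_sigma_deg == 30))
  m2 <- patchMetrics(tp)
  expect_equal(m2$pct_pd, 100)
  expect_equal(m2$pct_ed, 0)
  expect_equal(m2$pct_pd_only, 100)
  expect_error(patchMetrics(SigmaField(0, 0, 10)), "larger patch")
})

test_that("metrics are invariant under global axis rotation", {
  f <- generateSigmaField(8, 8, mixture = "calibrated", seed = 5)
  m0 <- patchMetrics(f)
  for (rot in c(17.3, 45, 89.9)) {
    cc <- latticeCoords(f)
    g <- SigmaField(cc$q, cc$r, (sigmaValues(f) + rot) %% 90)
    m1 <- patchMetrics(g)
    expect_equal(m1$pct_ed, m0$pct_ed)
    expect_equal(m1$pct_pd, m0$pct_pd)
    expect_equal(m1$delta_sigma_summary, m0$delta_sigma_summary)
  }
})

test_that("misalignment summary fractions are monotone", {
  f <- generateSigmaField(20, 20, mixture = "calibrated", seed = 6)
  s <- patchMetrics(f)$delta_sigma_summary
  expect_gte(s$within5, s$exact)
  expect_gte(s$ge15, s$ge20)
  expect_true(all(unlist(s) >= 0 & unlist(s) <= 1))
})
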