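test_that("expected pool coordinates hit the boundary and midpoint cases", {
  e <- expectedPoolCoordinates(c(0, 0.5, 1))
  expect_equal(e$pct_fam, c(0, 50, 100))
  expect_equal(e$pct_hex, c(100, 50, 0))
  expect_equal(e$angle_deg, c(0, 45, 90))
})

test_that("expected pool angle increases strictly with the fraction", {
  f <- seq(0, 1, by = 0.01)
  ang <- expectedPoolCoordinates(f)$angle_deg
  expect_true(all(diff(ang) > 0))
})

test_that("the mixing model inverts exactly at zero noise", {
  for (gains in list(c(fam = 1, hex = 1), c(fam = 1, hex = 0.6),
                     c(fam = 0.7, hex = 1))) {
    f <- seq(0, 1, by = 0.05)
    coords <- expectedPoolCoordinates(f, gains)
    est <- vapply(seq_along(f), function(i)
      estimateContamination(coords[i, ], gains)$estimate, numeric(1))
    expect_equal(est, f, tolerance = 1e-12)
  }

  # and end to end through the simulator at zero noise
  sim <- simulatePoolSeries(0.10, simConfig(seed = 1, noiseCv = 0))
  nw <- normalizePlate(sim$plate)$wells
  pool <- nw[nw$sample_id == "pool_10", ]
  expect_equal(estimateContamination(pool)$estimate, 0.10,
               tolerance = 1e-12)
  main <- nw[nw$sample_id == "ref_main", ]
  expect_equal(estimateContamination(main)$estimate, 0)
})

test_that("swapping main and contaminant lines maps the estimate to 1 - f", {
  f <- c(0.05, 0.2, 0.35)
  coords <- expectedPoolCoordinates(f)
  swapped <- data.frame(pct_fam = coords$pct_hex, pct_hex = coords$pct_fam)
  for (i in seq_along(f)) {
    fh <- estimateContamination(coords[i, ])$estimate
    fhSwap <- estimateContamination(swapped[i, ])$estimate
    expect_equal(fhSwap, 1 - fh, tolerance = 1e-12)
  }
})

test_that("fraction estimates are accurate under leaf-quality noise", {
  # Monte-Carlo check of the estimator against the generator truth. The
  # residual error is dominated by baseline leakage: min-max normalized
  # coordinates retain a small positive offset from the baseline term of
  # amplified wells, which biases small fractions upward by about 0.01
  # under the default generator (see the methods vignette). The bound is
  # the build-time Monte-Carlo value with headroom for seed variation.
  fractions <- c(0.01, 0.03, 0.05, 0.10, 0.50)
  errs <- c()
  for (seed in 1:20) {
    sim <- simulatePoolSeries(fractions, simConfig(seed = seed))
    nw <- normalizePlate(sim$plate)$wells
    for (i in seq_along(fractions)) {
      id <- sprintf("pool_%g", 100 * fractions[i])
      est <- estimateContamination(nw[nw$sample_id == id, ])$estimate
      errs <- c(errs, abs(est - fractions[i]))
    }
  }
  expect_lte(mean(errs), 0.025)
  # ... and the error vanishes when the baseline term is negligible
  simLow <- simulatePoolSeries(fractions, simConfig(seed = 1, baseline = 1))
  nwLow <- normalizePlate(simLow$plate)$wells
  errsLow <- vapply(seq_along(fractions), function(i) {
    id <- sprintf("pool_%g", 100 * fractions[i])
    abs(estimateContamination(nwLow[nwLow$sample_id == id, ])$estimate -
          fractions[i])
  }, numeric(1))
  expect_lte(mean(errsLow), 0.02)
})

test_that("a pool identical to the pure reference is never flagged", {
  refs <- referenceSet(c(0.5, 0.8, 0.3, 0.6), c(89, 90, 89.5, 88),
                       c(45, 44, 46, 45))
  pool <- data.frame(pct_fam = c(0.6, 0.9), pct_hex = c(99, 98))
  res <- detectContamination(pool, refs)
  expect_false(res@flagged)
  expect_equal(res@nearestReference, "main")
})

test_that("a half-contaminated pool clusters with the hybrid reference", {
  for (seed in 1:5) {
    sim <- simulatePoolSeries(0.5, simConfig(seed = seed))
    nw <- normalizePlate(sim$plate)$wells
    refs <- referencesFromWells(nw)
    res <- detectContamination(nw[nw$sample_id == "pool_50", ], refs,
                               poolId = "pool_50")
    expect_equal(res@nearestReference, "hybrid")
    expect_true(res@flagged)
  }
})

test_that("detection power at 10 percent exceeds power at 5 percent", {
  flags5 <- 0L; flags10 <- 0L
  for (seed in 1:20) {
    sim <- simulatePoolSeries(c(0.05, 0.10), simConfig(seed = seed))
    nw <- normalizePlate(sim$plate)$wells
    refs <- referencesFromWells(nw)
    f5 <- detectContamination(nw[nw$sample_id == "pool_5", ], refs)@flagged
    f10 <- detectContamination(nw[nw$sample_id == "pool_10", ], refs)@flagged
    flags5 <- flags5 + f5; flags10 <- flags10 + f10
  }
  expect_gt(flags10, flags5)
})

test_that("a zero-spread reference warns and falls back to the floor", {
  refs <- referenceSet(c(1, 1, 1), c(89, 90, 88), c(45, 44, 46))
  pool <- data.frame(pct_fam = rep(20, 4), pct_hex = rep(90, 4))
  expect_warning(res <- detectContamination(pool, refs), "floor")
  expect_true(is.finite(res@zScore))
})

test_that("an all-failed pool yields a no-estimate outcome", {
  pool <- data.frame(pct_fam = c(2, 3), pct_hex = c(1, 4))
  est <- estimateContamination(pool)
  expect_true(is.na(est$estimate))
  expect_equal(est$nAmplified, 0L)
  refs <- referenceSet(c(0.5, 0.8, 0.3), c(89, 90, 88), c(45, 44, 46))
  res <- detectContamination(pool, refs)
  expect_false(res@flagged)
  expect_true(is.na(res@estimatedFraction))
})

test_that("purity reports are deterministic tables", {
  expect_equal(nrow(purityReport(list())), 0L)
  refs <- referenceSet(c(0.5, 0.8, 0.3), c(89, 90, 88), c(45, 44, 46))
  p1 <- detectContamination(data.frame(pct_fam = 50, pct_hex = 50), refs,
                            poolId = "b_pool")
  p2 <- detectContamination(data.frame(pct_fam = 1, pct_hex = 99), refs,
                            poolId = "a_pool")
  rep <- purityReport(list(p1, p2))
  expect_equal(rep$pool_id, c("a_pool", "b_pool"))
  expect_equal(names(rep)[1:4],
               c("pool_id", "mean_angle", "z_score", "flagged"))
})

test_that("gain calibration recovers the gain ratio from the hybrid angle", {
  g <- c(fam = 0.8, hex = 1)
  hybrid <- expectedPoolCoordinates(0.5, g)
  est <- gainsFromHybrid(hybrid$angle_deg)
  expect_equal(est[["fam"]] / est[["hex"]], 0.8, tolerance = 1e-12)
})
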