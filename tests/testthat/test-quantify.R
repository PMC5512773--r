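test_that("raw density is total spots over total length", {
  expect_identical(rawDensity(0, 1e4), 0)
  expect_equal(rawDensity(10, 1e4), 1e-3)
  expect_error(rawDensity(5, 0), "undefined density")
  # pooling = density of concatenated totals, not mean of densities
  nA <- 12; lA <- 5e3; nB <- 40; lB <- 2e4
  pooled <- rawDensity(nA + nB, lA + lB)
  expect_equal(pooled, (nA + nB) / (lA + lB))
  expect_false(isTRUE(all.equal(pooled,
                                mean(c(nA / lA, nB / lB)))))
})

test_that("convergence curve accumulates and flags plateaus", {
  # single molecule: one point, never converged
  cc1 <- convergenceCurve(100, 3)
  expect_identical(nrow(cc1@points), 1L)
  expect_false(cc1@converged)
  # large stable sample converges near the true rate
  set.seed(3)
  lens <- runif(1500, 40, 120)
  spots <- rpois(1500, lens * 0.02)
  cc <- convergenceCurve(lens, spots)
  expect_true(all(diff(cc@points$cumLengthPx) > 0))
  expect_true(cc@converged)
  expect_equal(cc@points$density[1500], sum(spots) / sum(lens))
  expect_lt(abs(cc@points$density[1500] - 0.02) / 0.02, 0.05)
  # an early-unstable, late-jumping sequence does not converge
  lens2 <- rep(100, 50)
  spots2 <- c(rep(1, 40), rep(30, 10))
  expect_false(convergenceCurve(lens2, spots2)@converged)
  # final density of the same molecules is order-invariant
  o <- sample(1500)
  cc.perm <- convergenceCurve(lens[o], spots[o])
  expect_equal(cc.perm@points$density[1500], cc@points$density[1500])
})

test_that("all-empty samples converge only if trailing densities are zero", {
  cc0 <- convergenceCurve(rep(100, 50), rep(0, 50))
  expect_identical(cc0@points$density[50], 0)
  expect_true(cc0@converged)
})

test_that("split-half SD follows the two-value SD formula", {
  # two equal-length molecules force one per group: densities 0.0040 and
  # 0.0044, SD = |d1-d2|/sqrt(2) = 2.83e-4, mean 0.0042 -> 6.73%
  res <- splitHalfSD(c(1e4, 1e4), c(40, 44), seed = 1L)
  expect_equal(res$relativeSD, (4e-4 / sqrt(2)) / 0.0042 * 100,
               tolerance = 1e-9)
  expect_equal(res$relativeSD, 6.73, tolerance = 1e-2)
  expect_true(res$balanced)
  # identical group densities give zero
  expect_equal(splitHalfSD(c(1e4, 1e4), c(40, 40), seed = 1L)$relativeSD, 0)
  expect_error(splitHalfSD(100, 3), "at least 2")
})

test_that("groups are DNA-balanced and a dominant molecule is flagged", {
  set.seed(9)
  lens <- runif(200, 30, 150)
  spots <- rpois(200, lens * 0.02)
  res <- splitHalfSD(lens, spots, seed = 5L)
  expect_true(res$balanced)
  expect_lt(abs(diff(res$groupLengthsPx)) / mean(res$groupLengthsPx), 0.05)
  expect_identical(sum(res$groupSpots), sum(spots))
  # one molecule holding most DNA cannot be balanced
  expect_warning(
    bad <- splitHalfSD(c(1e5, 10, 12), c(100, 1, 1), seed = 2L),
    "balance")
  expect_false(bad$balanced)
  expect_true(is.finite(bad$relativeSD))
})

test_that("split-half SD shrinks as the sample grows", {
  med <- vapply(c(30, 300, 3000), function(n) {
    vals <- vapply(1:11, function(s) {
      set.seed(s)
      lens <- runif(n, 40, 120)
      spots <- rpois(n, lens * 0.02)
      splitHalfSD(lens, spots, seed = s)$relativeSD
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
  expect_lt(med[3], 5)
})

test_that("the estimator is nearly unbiased with well-separated marks", {
  # ideal settings: eps = 1, marks so sparse (1e-5/bp, mean gap ~180 px)
  # that diffraction merging is negligible, ~50 Mb of DNA
  sim <- simulateSample(sceneSpec(markDensity = 1e-5, seed = 4000L),
                        nScenes = 19L, config = runConfig(seed = 4000L))
  est <- samplePercent(sim$result)
  expect_gte(sim$truthTotals$totalBp, 5e7)
  expect_lt(abs(est - 100 * 1e-5) / (100 * 1e-5), 0.05)
})

test_that("calibration converts density to %5hmC per its formula", {
  m0 <- calibrationModel()
  expect_identical(percent5hmC(0, m0), 0)
  # worked example: D = 1e-3, C = 1.2, eps = 0.8, 160 nm px, s = 0.85
  m <- calibrationModel(labellingEfficiency = 0.8, stretchFactor = 0.85,
                        pixelSizeNm = 160, clusterCorrection = 1.2)
  expect_equal(bpPerPx(m), 160 / (0.34 * 0.85), tolerance = 1e-12)
  expect_equal(percent5hmC(1e-3, m), 100 * (1e-3 * 1.2 / 0.8) / 553.633,
               tolerance = 1e-4)
  expect_equal(percent5hmC(1e-3, m), 2.71e-4, tolerance = 1e-2)
  # linear in D: doubling density doubles the output exactly
  expect_identical(percent5hmC(2e-3, m), 2 * percent5hmC(1e-3, m))
  # labelling efficiency 0 is rejected at model construction
  expect_error(calibrationModel(labellingEfficiency = 0),
               "labellingEfficiency")
})

test_that("side-by-side reference normalization rescales the estimate", {
  m <- calibrationModel(referenceKnownPercent = 0.0059,
                        referenceMeasuredDensity = 2e-2)
  # the reference sample itself must read back its known value
  expect_equal(percent5hmC(2e-2, m), 0.0059, tolerance = 1e-12)
  # and the mapping stays linear
  expect_equal(percent5hmC(1e-2, m), 0.0059 / 2, tolerance = 1e-12)
  expect_error(calibrationModel(referenceKnownPercent = 0.0059),
               "together")
})

test_that("group comparison reports means, fold change and a p-value", {
  a <- c(0.0059, 0.0062, 0.0055, 0.0061)
  b <- c(0.0028, 0.0031, 0.0025, 0.0027)
  res <- compareGroups(a, b)
  expect_equal(res$foldChange, mean(a) / mean(b))
  expect_lt(res$pValue, 0.001)
  expect_identical(res$test, "welch")
  # identical groups: fold change 1, p = 1
  same <- c(0.001, 0.002, 0.003)
  res0 <- compareGroups(same, same)
  expect_equal(res0$foldChange, 1)
  expect_equal(res0$pValue, 1)
  # rank test variant
  resW <- compareGroups(a, b, test = "wilcoxon")
  expect_lt(resW$pValue, 0.05)
  expect_error(compareGroups(0.001, c(0.1, 0.2)), "at least 2")
})
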