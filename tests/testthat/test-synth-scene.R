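test_that("scene with zero mark density has an empty label channel", {
  spec <- sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
                    nMolecules = 5L, markDensity = 0, seed = 3L)
  sc <- renderScene(spec)
  truth <- sceneTruth(sc)
  expect_identical(truth@totals$nMarks, 0L)
  expect_identical(nrow(truth@marks), 0L)
  # label channel is pure background noise: no detections
  lab <- sceneChannels(sc)[, , 2]
  storage.mode(lab) <- "double"
  expect_identical(nrow(detectSpots(lab)), 0L)
})

test_that("rendered molecule length follows the bp-to-pixel geometry", {
  # 55,000 bp at 0.34 nm/bp, stretch 0.85, 160 nm pixels -> 99.34 px
  spec <- sceneSpec(imageHeightPx = 128L, imageWidthPx = 128L,
                    nMolecules = 1L, fragmentLengthBpMean = 55000,
                    fragmentLengthBpSigma = 0, stretchFactor = 0.85,
                    orientationDegSigma = 0, pixelSizeNm = 160, seed = 2L)
  truth <- sceneTruth(renderScene(spec))
  expect_equal(truth@molecules$contourLengthBp, 55000)
  expect_equal(truth@molecules$lengthPx, 55000 * 0.34 * 0.85 / 160,
               tolerance = 1e-12)
  expect_equal(truth@molecules$lengthPx, 99.3, tolerance = 1e-3)
  # endpoint distance agrees with the recorded length
  with(truth@molecules,
       expect_equal(sqrt((r1 - r0)^2 + (c1 - c0)^2), lengthPx,
                    tolerance = 1e-9))
})

test_that("geometry invariant holds for every molecule across seeds", {
  for (s in 1:3) {
    truth <- sceneTruth(renderScene(sceneSpec(
      imageHeightPx = 512L, imageWidthPx = 512L, nMolecules = 25L,
      seed = s)))
    expected <- truth@molecules$contourLengthBp * 0.34 * 0.85 / 160
    expect_true(all(abs(truth@molecules$lengthPx - expected) < 1))
    # totals equal sums over molecules
    expect_equal(truth@totals$totalBp, sum(truth@molecules$contourLengthBp))
    expect_equal(truth@totals$nLabelled, sum(truth@molecules$nLabelled))
  }
})

test_that("identical spec and seed render bit-identical scenes", {
  spec <- sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
                    nMolecules = 8L, seed = 42L)
  a <- renderScene(spec); b <- renderScene(spec)
  expect_identical(sceneChannels(a), sceneChannels(b))
  expect_identical(sceneTruth(a)@molecules, sceneTruth(b)@molecules)
  expect_identical(sceneTruth(a)@marks, sceneTruth(b)@marks)
  c <- renderScene(sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
                             nMolecules = 8L, seed = 43L))
  expect_false(identical(sceneChannels(a), sceneChannels(c)))
})

test_that("mark and labelling statistics converge to spec probabilities", {
  # high density so counts are informative at modest rendering cost
  spec <- sceneSpec(imageHeightPx = 512L, imageWidthPx = 512L,
                    nMolecules = 40L, markDensity = 1e-3,
                    labellingEfficiency = 0.7, seed = 9L)
  tot <- data.frame(bp = 0, marks = 0, lab = 0)
  for (s in 1:3) {
    sp <- spec; sp@seed <- s
    t <- sceneTruth(renderScene(sp))@totals
    tot$bp <- tot$bp + t$totalBp
    tot$marks <- tot$marks + t$nMarks
    tot$lab <- tot$lab + t$nLabelled
  }
  rate <- tot$marks / tot$bp
  se <- sqrt(1e-3 / tot$bp)
  expect_lt(abs(rate - 1e-3), 4 * se)
  labFrac <- tot$lab / tot$marks
  seLab <- sqrt(0.7 * 0.3 / tot$marks)
  expect_lt(abs(labFrac - 0.7), 4 * seLab)
})

test_that("molecules that cannot fit are clipped with consistent truth", {
  # 300 kbp molecule cannot fit in a 64 px field: must be clipped
  spec <- sceneSpec(imageHeightPx = 64L, imageWidthPx = 64L,
                    nMolecules = 1L, fragmentLengthBpMean = 3e5,
                    fragmentLengthBpSigma = 0, orientationDegSigma = 0,
                    seed = 1L)
  truth <- sceneTruth(renderScene(spec))
  expect_true(truth@molecules$clipped)
  expect_lt(truth@molecules$contourLengthBp, 3e5)
  expect_equal(truth@molecules$lengthPx,
               truth@molecules$contourLengthBp * 0.34 * 0.85 / 160,
               tolerance = 1e-9)
  # endpoints inside the field
  expect_true(all(unlist(truth@molecules[, c("r0", "r1")]) <= 64))
  expect_true(all(unlist(truth@molecules[, c("c0", "c1")]) <= 64))
})

test_that("bleach trace generator produces the requested staircase", {
  # zero fluorophores: constant at background
  tr0 <- renderBleachTrace(bleachTraceSpec(nFluorophores = 0L,
                                           noiseSigma = 0, seed = 1L))
  expect_identical(unique(tr0$intensity), 50)
  expect_identical(tr0$stepCount, 0L)
  # noiseless 2-fluorophore trace: exactly 3 levels, 2 downward jumps
  tr2 <- renderBleachTrace(bleachTraceSpec(nFluorophores = 2L,
                                           noiseSigma = 0, seed = 5L))
  lev <- unique(tr2$intensity)
  expect_identical(length(lev), 3L)
  jumps <- diff(tr2$intensity)
  expect_identical(sum(jumps < 0), 2L)
  expect_true(all(jumps <= 0))
  expect_equal(tr2$intensity[length(tr2$intensity)], 50)
  # determinism
  expect_identical(tr2$intensity, renderBleachTrace(
    bleachTraceSpec(nFluorophores = 2L, noiseSigma = 0, seed = 5L))$intensity)
  # too few frames for the steps
  expect_error(bleachTraceSpec(nFluorophores = 5L, frames = 6L),
               "frames too few")
})

test_that("preset catalogue spans the observed tissue densities", {
  pres <- presetScenarios()
  expect_equal(pres$healthy_colon@markDensity, 5.9e-5)
  expect_equal(pres$cll@markDensity, 1.9e-5)
  expect_equal(pres$healthy_blood@markDensity, 4.2e-5)
  expect_equal(pres$crc@markDensity, 2.8e-5)
  expect_true(all(vapply(pres, function(p) p@markDensity, numeric(1)) >=
                    1.9e-5))
  expect_true(all(vapply(pres, function(p) p@markDensity, numeric(1)) <=
                    5.9e-5))
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(sceneSpec(markDensity = 1.5), "markDensity")
  expect_error(sceneSpec(stretchFactor = 0), "stretchFactor")
  expect_error(sceneSpec(pixelSizeNm = -1), "pixelSizeNm")
})
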