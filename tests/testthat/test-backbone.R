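test_that("path length uses unit axial and sqrt(2) diagonal step costs", {
  expect_equal(traceLengthPx(cbind(1L, 1:101)), 100)
  expect_equal(traceLengthPx(cbind(1:11, 1:11)), 10 * sqrt(2))
  # mixed path: 3 axial + 2 diagonal steps
  p <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 4), c(3, 5), c(3, 6))
  expect_equal(traceLengthPx(p), 3 + 2 * sqrt(2))
  expect_warning(len <- traceLengthPx(matrix(c(1, 1), 1)), "undefined")
  expect_identical(len, 0)
})

test_that("a noise-only channel yields no molecules", {
  set.seed(10)
  img <- cameraNoise(matrix(0, 256, 256), 20, 30, 20)
  storage.mode(img) <- "double"
  seg <- segmentBackbones(img)
  expect_identical(length(seg$molecules), 0L)
})

test_that("well-separated molecules are each recovered with accurate length", {
  # find a seeded scene whose 20 molecules are pairwise well separated
  spec <- NULL; truth <- NULL
  for (s in 1:50) {
    cand <- sceneSpec(imageHeightPx = 700L, imageWidthPx = 700L,
                      nMolecules = 20L, seed = s)
    tr <- sceneTruth(renderScene(cand))@molecules
    ts <- seq(0, 1, 0.25)
    pts <- do.call(rbind, lapply(ts, function(t)
      cbind(tr$r0 + t * (tr$r1 - tr$r0), tr$c0 + t * (tr$c1 - tr$c0))))
    mol <- rep(seq_len(nrow(tr)), times = length(ts))
    d <- as.matrix(dist(pts))
    d[outer(mol, mol, "==")] <- Inf   # ignore intra-molecule distances
    if (min(d) > 12) { spec <- cand; truth <- tr; break }
  }
  expect_false(is.null(spec))
  sc <- renderScene(spec)
  img <- sceneChannels(sc)[, , 1]
  storage.mode(img) <- "double"
  seg <- segmentBackbones(img)
  expect_identical(length(seg$molecules), 20L)
  # greedy match each trace to the nearest ground-truth molecule
  used <- logical(20)
  relErr <- numeric(20)
  for (i in seq_along(seg$molecules)) {
    m <- seg$molecules[[i]]
    ctr <- colMeans(tracePath(m))
    d <- sqrt((ctr[1] - (truth$r0 + truth$r1) / 2)^2 +
                (ctr[2] - (truth$c0 + truth$c1) / 2)^2)
    j <- which.min(d)
    expect_false(used[j])
    used[j] <- TRUE
    relErr[i] <- abs(lengthPx(m) - truth$lengthPx[j]) / truth$lengthPx[j]
  }
  expect_true(all(used))
  # total length error below 5% on a high-SNR well-separated scene
  expect_lt(abs(sum(vapply(seg$molecules, lengthPx, numeric(1))) -
                  sum(truth$lengthPx)) / sum(truth$lengthPx), 0.05)
  expect_lt(max(relErr), 0.08)
})

test_that("measured total length never exceeds ground truth by > 5%", {
  sc <- renderScene(sceneSpec(imageHeightPx = 512L, imageWidthPx = 512L,
                              nMolecules = 15L, seed = 21L))
  img <- sceneChannels(sc)[, , 1]
  storage.mode(img) <- "double"
  seg <- segmentBackbones(img)
  measured <- sum(vapply(seg$molecules, lengthPx, numeric(1)))
  expect_lte(measured, sum(sceneTruth(sc)@molecules$lengthPx) * 1.05)
})

test_that("crossing molecules are discarded and flagged branched", {
  # X-shaped pair rendered deliberately, plus one clean molecule
  ideal <- renderSegments(rbind(c(30, 20, 90, 100),
                                c(90, 20, 30, 100),
                                c(150, 20, 150, 120)),
                          c(200, 200), 85 / 160, 60)
  set.seed(2)
  img <- cameraNoise(ideal, 20, 30, 20)
  storage.mode(img) <- "double"
  seg <- segmentBackbones(img)
  expect_identical(length(seg$molecules), 1L)      # only the clean one
  expect_true("branched" %in% seg$discards$reason)
  # the retained trace is the horizontal molecule at row 150
  expect_lt(abs(mean(tracePath(seg$molecules[[1]])[, 1]) - 150), 2)
})

test_that("border-touching objects are discarded", {
  ideal <- renderSegments(c(40, -10, 40, 60), c(80, 80), 85 / 160, 60)
  set.seed(3)
  img <- cameraNoise(ideal, 20, 30, 20)
  storage.mode(img) <- "double"
  seg <- segmentBackbones(img)
  expect_identical(length(seg$molecules), 0L)
  expect_true("border" %in% seg$discards$reason)
})

test_that("length measurement is rotation tolerant", {
  lens <- vapply(c(0, 45), function(ang) {
    spec <- sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
                      nMolecules = 1L, fragmentLengthBpMean = 40000,
                      fragmentLengthBpSigma = 0, orientationDegMean = ang,
                      orientationDegSigma = 0, seed = 6L)
    sc <- renderScene(spec)
    img <- sceneChannels(sc)[, , 1]
    storage.mode(img) <- "double"
    seg <- segmentBackbones(img)
    expect_identical(length(seg$molecules), 1L)
    lengthPx(seg$molecules[[1]])
  }, numeric(1))
  expect_lt(abs(lens[1] - lens[2]) / mean(lens), 0.05)
})

test_that("segmentation is idempotent on the same image", {
  sc <- renderScene(sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
                              nMolecules = 6L, seed = 13L))
  img <- sceneChannels(sc)[, , 1]
  storage.mode(img) <- "double"
  a <- segmentBackbones(img)
  b <- segmentBackbones(img)
  expect_identical(length(a$molecules), length(b$molecules))
  for (i in seq_along(a$molecules))
    expect_identical(tracePath(a$molecules[[i]]), tracePath(b$molecules[[i]]))
})

test_that("thinning reduces a thick bar to a single 8-connected path", {
  m <- matrix(FALSE, 15, 40)
  m[6:9, 4:36] <- TRUE
  sk <- thinMask(m)
  deg <- fiberHMC:::neighborCount8(sk)
  expect_true(all(deg[sk] <= 2))
  expect_identical(sum(sk & deg == 1), 2L)
})

test_that("invalid input is rejected", {
  expect_error(segmentBackbones(array(0, c(4, 4, 2))), "2-D")
  expect_error(segmentBackbones(matrix(as.numeric(1:256), 16, 16),
                                list(threshold = -2)), "threshold")
})
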