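mkTrace <- function(id, path) {
  new("MoleculeTrace", id = as.integer(id), path = path,
      lengthPx = traceLengthPx(path), meanIntensity = 1,
      flags = character(0))
}

mkSpots <- function(rows, cols) {
  data.frame(row = rows, col = cols, peak = 1, integrated = 1, score = 10)
}

test_that("spots on a path are assigned, distant spots are orphans", {
  tr <- mkTrace(1L, cbind(10L, 5:30))
  # on-path, within tolerance, and beyond tolerance (maxDist + 1)
  sp <- mkSpots(c(10, 11.5, 13), c(12, 20, 25))
  res <- assignSpots(list(tr), sp, maxDistPx = 2)
  expect_identical(res$assignments$molecule, c(1L, 1L, NA))
  expect_equal(res$assignments$distancePx[1], 0)
  expect_equal(res$assignments$distancePx[2], 1.5)
  expect_identical(nrow(res$orphans), 1L)
  expect_identical(spotCount(res$molecules[[1]]), 2L)
})

test_that("equidistant spots break ties towards the lower molecule id", {
  trA <- mkTrace(1L, cbind(10L, 5:30))
  trB <- mkTrace(2L, cbind(14L, 5:30))
  sp <- mkSpots(12, 15)  # exactly 2 px from each path
  res <- assignSpots(list(trA, trB), sp, maxDistPx = 2)
  expect_identical(res$assignments$molecule, 1L)
  # and identically when the list order is reversed
  res2 <- assignSpots(list(trB, trA), sp, maxDistPx = 2)
  expect_identical(res2$assignments$molecule, 1L)
})

test_that("assigned plus orphan counts equal total detections", {
  for (s in 1:3) {
    sc <- renderScene(sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
                                nMolecules = 6L, markDensity = 3e-4,
                                seed = s))
    res <- analyzeScene(sc)
    expect_identical(sum(res$perMolecule$nSpots) + nrow(res$orphans),
                     nrow(res$spots))
    expect_identical(sum(!is.na(res$assignments$molecule)) +
                       sum(is.na(res$assignments$molecule)),
                     nrow(res$spots))
  }
})

test_that("enlarging the tolerance never decreases assignments", {
  sc <- renderScene(sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
                              nMolecules = 6L, markDensity = 3e-4,
                              seed = 4L))
  img <- sceneChannels(sc)
  bb <- segmentBackbones(`storage.mode<-`(img[, , 1], "double"))
  sp <- detectSpots(`storage.mode<-`(img[, , 2], "double"))
  counts <- vapply(c(0.5, 1, 2, 4, 8), function(d)
    sum(!is.na(assignSpots(bb$molecules, sp, d)$assignments$molecule)),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("assigned spots match ground-truth labelled marks when isolated", {
  # marks far apart (> 4 PSF sigma) on well-separated molecules: counts
  # agree exactly with ground truth per molecule
  nChecked <- 0L
  for (s in 1:20) {
    cand <- sceneSpec(imageHeightPx = 400L, imageWidthPx = 400L,
                      nMolecules = 5L, markDensity = 8e-5, seed = s)
    sc <- renderScene(cand)
    tr <- sceneTruth(sc)@molecules
    mk <- sceneTruth(sc)@marks
    ts <- seq(0, 1, 0.25)
    pts <- do.call(rbind, lapply(ts, function(t)
      cbind(tr$r0 + t * (tr$r1 - tr$r0), tr$c0 + t * (tr$c1 - tr$c0))))
    mol <- rep(seq_len(nrow(tr)), times = length(ts))
    dd <- as.matrix(dist(pts))
    dd[outer(mol, mol, "==")] <- Inf
    sepMol <- min(dd) > 15
    sepMarks <- nrow(mk) < 2 ||
      min(dist(as.matrix(mk[, c("row", "col")]))) > 4 * 130 / 160
    if (!sepMol || !sepMarks || nrow(mk) == 0) next
    res <- analyzeScene(sc)
    if (nrow(res$perMolecule) != nrow(tr)) next
    # match traces to truth molecules by centre and compare counts
    for (i in seq_len(nrow(res$perMolecule))) {
      m <- res$molecules[[i]]
      ctr <- colMeans(tracePath(m@trace))
      j <- which.min((ctr[1] - (tr$r0 + tr$r1) / 2)^2 +
                       (ctr[2] - (tr$c0 + tr$c1) / 2)^2)
      expect_identical(spotCount(m), tr$nLabelled[j])
    }
    nChecked <- nChecked + 1L
  }
  expect_gte(nChecked, 1L)
})

test_that("the channel registration offset shifts spot coordinates", {
  tr <- mkTrace(1L, cbind(10L, 5:30))
  sp <- mkSpots(13, 15)  # 3 px off the path
  res0 <- assignSpots(list(tr), sp, maxDistPx = 2)
  expect_true(is.na(res0$assignments$molecule))
  resOff <- assignSpots(list(tr), sp, maxDistPx = 2, offsetPx = c(-3, 0))
  expect_identical(resOff$assignments$molecule, 1L)
})

test_that("invalid tolerance is rejected", {
  expect_error(assignSpots(list(), mkSpots(1, 1), maxDistPx = 0),
               "maxDistPx")
})
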