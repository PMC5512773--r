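## End-to-end pipeline: image(s) -> traces -> spots -> colocalization ->
## sample-level density, QC statistics and calibrated %5hmC.

#' Analyze one two-channel scene
#'
#' Segments and traces backbones in the backbone channel, detects spots
#' in the label channel and colocalizes them. The two channels must have
#' identical dimensions (registered acquisition); a constant label
#' channel offset can be supplied through `config`.
#'
#' @param scene a [FiberScene-class], a `h x w x 2` array, or a path to
#'   a 2-page TIFF.
#' @param config a [RunConfig-class].
#' @return List: `molecules` (list of [LabeledMolecule-class]),
#'   `spots` (full detection table), `orphans`, `assignments`,
#'   `discards`, and `perMolecule` (data.frame `molecule`, `lengthPx`,
#'   `nSpots`, `meanIntensity`).
#' @examples
#' sc <- renderScene(sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
#'                             nMolecules = 4L, markDensity = 2e-4,
#'                             seed = 11L))
#' res <- analyzeScene(sc)
#' res$perMolecule
#' @export
analyzeScene <- function(scene, config = runConfig()) {
  stopifnot(is(config, "RunConfig"))
  arr <- if (is(scene, "FiberScene")) {
    sceneChannels(scene)
  } else if (is.character(scene)) {
    readScene(scene, pages = unname(config@channels[c("backbone", "label")]))
  } else {
    scene
  }
  if (length(dim(arr)) != 3L)
    stop("scene must be a height x width x channel array")
  bb.ch <- if (is(scene, "FiberScene") || is.character(scene)) 1L else
    unname(config@channels[["backbone"]])
  lb.ch <- if (is(scene, "FiberScene") || is.character(scene)) 2L else
    unname(config@channels[["label"]])
  backbone.img <- arr[, , bb.ch]
  label.img <- arr[, , lb.ch]
  if (!identical(dim(backbone.img), dim(label.img)))
    stop("channel shape mismatch: backbone and label channels must be registered")

  seg <- segmentBackbones(backbone.img,
                          modifyList(backboneParams(), config@backbone))
  spots <- detectSpots(label.img, modifyList(spotParams(), config@spots))
  maxDist <- config@colocal$maxDistPx %||% 2
  offset <- config@colocal$offsetPx %||% c(0, 0)
  asg <- assignSpots(seg$molecules, spots, maxDistPx = maxDist,
                     offsetPx = offset)
  perMolecule <- data.frame(
    molecule = vapply(seg$molecules, function(m) m@id, integer(1)),
    lengthPx = vapply(seg$molecules, function(m) m@lengthPx, numeric(1)),
    nSpots = vapply(asg$molecules, spotCount, integer(1)),
    meanIntensity = vapply(seg$molecules, function(m) m@meanIntensity,
                           numeric(1)))
  list(molecules = asg$molecules, spots = spots, orphans = asg$orphans,
       assignments = asg$assignments, discards = seg$discards,
       perMolecule = perMolecule)
}

#' Quantify a sample from a set of scenes
#'
#' Runs [analyzeScene()] on every image of a sample, pools molecules and
#' spots by summing (density of the concatenated totals), and computes
#' the convergence curve, the split-half reproducibility statistic and —
#' given calibration constants — the absolute %5hmC/dNTPs.
#'
#' @param scenes list of scenes ([FiberScene-class] objects, arrays, or
#'   TIFF paths), in acquisition order.
#' @param config a [RunConfig-class]; its `calibration` converts density
#'   to %5hmC and its `seed` drives the split-half shuffle.
#' @return A [SampleResult-class].
#' @examples
#' scs <- lapply(1:2, function(s) renderScene(
#'   sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L, nMolecules = 6L,
#'             markDensity = 2e-4, seed = s)))
#' res <- quantifySample(scs, runConfig())
#' sampleDensity(res)
#' @export
quantifySample <- function(scenes, config = runConfig()) {
  stopifnot(is(config, "RunConfig"))
  if (!is.list(scenes)) scenes <- list(scenes)
  per <- vector("list", length(scenes))
  nOrphans <- 0L
  for (k in seq_along(scenes)) {
    res <- analyzeScene(scenes[[k]], config)
    pm <- res$perMolecule
    if (nrow(pm)) pm <- cbind(scene = k, pm)
    else pm <- data.frame(scene = integer(), molecule = integer(),
                          lengthPx = numeric(), nSpots = integer(),
                          meanIntensity = numeric())
    per[[k]] <- pm
    nOrphans <- nOrphans + nrow(res$orphans)
  }
  perMolecule <- do.call(rbind, per)
  totals <- list(totalLengthPx = sum(perMolecule$lengthPx),
                 totalSpots = as.integer(sum(perMolecule$nSpots)),
                 nMolecules = nrow(perMolecule),
                 nOrphans = nOrphans)
  dens <- if (totals$totalLengthPx > 0)
    rawDensity(totals$totalSpots, totals$totalLengthPx) else NA_real_
  conv <- if (nrow(perMolecule)) {
    do.call(convergenceCurve,
            c(list(lengthsPx = perMolecule$lengthPx,
                   nSpots = perMolecule$nSpots), config@convergence))
  } else {
    NULL
  }
  sh <- if (nrow(perMolecule) >= 2L) {
    do.call(splitHalfSD,
            c(list(lengthsPx = perMolecule$lengthPx,
                   nSpots = perMolecule$nSpots, seed = config@seed),
              config@splitHalf))
  } else {
    list()
  }
  pct <- if (!is.na(dens)) percent5hmC(dens, config@calibration) else
    NA_real_
  new("SampleResult", perMolecule = perMolecule, totals = totals,
      rawDensity = dens, percent5hmC = pct,
      convergence = conv, splitHalf = sh,
      calibration = config@calibration, seed = config@seed)
}

#' Estimate the cluster correction from simulated photobleaching
#'
#' Reproduces, on synthetic scenes, the photobleaching experiment that
#' measures how many fluorophores hide inside each detected spot: scenes
#' are rendered and analyzed, every labelled ground-truth mark is matched
#' to its nearest assigned spot (within `matchRadiusPx`), and each spot's
#' matched fluorophore count parameterizes a simulated bleaching trace.
#' The traces are then fitted with [fitSteps()] and summarized by
#' [clusterDistribution()] / [clusterCorrection()], exercising the same
#' estimation path a real bleaching movie would.
#'
#' @param spec a [SceneSpec-class]; scenes use seeds `spec@seed`,
#'   `spec@seed + 1`, ...
#' @param nScenes fields of view to pool spots from.
#' @param config a [RunConfig-class] for the analysis stages.
#' @param traceSpec a [BleachTraceSpec-class] template for the simulated
#'   traces (its `nFluorophores` and `seed` are overridden per spot).
#' @param matchRadiusPx mark-to-spot matching radius; default 2.5 px
#'   (~one resolvable-site radius).
#' @param Kmax largest cluster size tracked.
#' @return List: `dist` (the [ClusterDist-class]), `C` (the correction
#'   factor) and `nSpots` (traces analyzed).
#' @examples
#' est <- simulateClusterCorrection(sceneSpec(imageHeightPx = 256L,
#'   imageWidthPx = 256L, nMolecules = 8L, markDensity = 3e-4,
#'   seed = 2L), nScenes = 1L)
#' est$C
#' @export
simulateClusterCorrection <- function(spec, nScenes = 3L,
                                      config = runConfig(),
                                      traceSpec = bleachTraceSpec(
                                        noiseSigma = 10),
                                      matchRadiusPx = 2.5, Kmax = 5L) {
  stopifnot(is(spec, "SceneSpec"))
  counts <- integer(0)
  for (k in seq_len(nScenes)) {
    sp <- spec
    sp@seed <- as.integer(spec@seed + k - 1L)
    sc <- renderScene(sp)
    res <- analyzeScene(sc, config)
    mk <- sceneTruth(sc)@marks
    mk <- mk[mk$labelled, , drop = FALSE]
    asg <- do.call(rbind, lapply(res$molecules, function(m)
      m@spots[, c("row", "col"), drop = FALSE]))
    if (is.null(asg) || !nrow(asg) || !nrow(mk)) next
    hit <- vapply(seq_len(nrow(mk)), function(i) {
      d2 <- (asg$row - mk$row[i])^2 + (asg$col - mk$col[i])^2
      j <- which.min(d2)
      if (d2[j] <= matchRadiusPx^2) j else NA_integer_
    }, integer(1))
    tab <- tabulate(hit[!is.na(hit)], nbins = nrow(asg))
    counts <- c(counts, tab[tab >= 1L])
  }
  if (!length(counts))
    stop("no matched spots: increase nScenes or markDensity")
  base <- spec@seed %% 100000000L
  fits <- lapply(seq_along(counts), function(i) {
    ts <- traceSpec
    ts@nFluorophores <- counts[i]
    ts@seed <- as.integer(base + i)
    fitSteps(renderBleachTrace(ts)$intensity)
  })
  cd <- clusterDistribution(fits, Kmax)
  list(dist = cd, C = clusterCorrection(cd), nSpots = length(counts))
}

#' Simulate and quantify a whole sample
#'
#' Convenience wrapper used throughout validation: renders `nScenes`
#' fields of view from a [SceneSpec-class] (seeds `seed, seed + 1, ...`)
#' and quantifies them as one sample.
#'
#' @param spec a [SceneSpec-class]; its `seed` slot is overridden per
#'   scene.
#' @param nScenes number of fields of view.
#' @param config a [RunConfig-class].
#' @param seed base seed for the scene series.
#' @return List: `result` (the [SampleResult-class]) and `truthDensity`
#'   (ground-truth labelled marks per rendered bp, aggregated over the
#'   scenes) plus `truthTotals`.
#' @examples
#' sim <- simulateSample(sceneSpec(imageHeightPx = 256L,
#'   imageWidthPx = 256L, nMolecules = 6L, markDensity = 2e-4), 2L)
#' sampleDensity(sim$result)
#' @export
simulateSample <- function(spec, nScenes = 1L, config = runConfig(),
                           seed = spec@seed) {
  stopifnot(is(spec, "SceneSpec"))
  scenes <- vector("list", nScenes)
  totBp <- 0; totMarks <- 0L; totLab <- 0L; totPx <- 0
  for (k in seq_len(nScenes)) {
    sp <- spec
    sp@seed <- as.integer(seed + k - 1L)
    sc <- renderScene(sp)
    scenes[[k]] <- sc
    tt <- sceneTruth(sc)@totals
    totBp <- totBp + tt$totalBp
    totPx <- totPx + tt$totalLengthPx
    totMarks <- totMarks + tt$nMarks
    totLab <- totLab + tt$nLabelled
  }
  res <- quantifySample(scenes, config)
  list(result = res,
       truthDensity = if (totBp > 0) totLab / totBp else NA_real_,
       truthTotals = list(totalBp = totBp, totalLengthPx = totPx,
                          nMarks = totMarks, nLabelled = totLab))
}
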