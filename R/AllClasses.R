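## S4 classes for the simulator, detection and quantification layers.
## Coordinates are 1-based (row, col); a pixel's centre sits at its
## integer coordinate, so subpixel positions interpolate between centres.

#' Parameters of one simulated field of view
#'
#' A `SceneSpec` fully determines a two-channel synthetic image of
#' stretched DNA molecules: field geometry, molecule population, 5hmC
#' mark statistics, optics and camera noise. Identical specs (including
#' `seed`) render bit-identical scenes.
#'
#' @slot imageHeightPx,imageWidthPx field size in pixels.
#' @slot pixelSizeNm physical size of one pixel (nm), > 0.
#' @slot nMolecules number of molecules placed in the field.
#' @slot fragmentLengthBpMean expected molecule length in bases; lengths
#'   are drawn lognormal with this mean.
#' @slot fragmentLengthBpSigma lognormal spread (sdlog) of lengths.
#' @slot stretchFactor extension relative to B-form contour (0.34 nm/bp);
#'   dimensionless, in (0, 1.1].
#' @slot orientationDegSigma angular jitter (degrees, SD) around the
#'   horizontal stretching axis.
#' @slot markDensity probability per base of carrying 5hmC — the quantity
#'   the pipeline must recover (fraction of bases, e.g. 5.9e-5 = 0.0059%).
#' @slot labellingEfficiency probability a mark carries a fluorophore.
#' @slot psfSigmaNm Gaussian PSF sigma per channel, named
#'   `c(backbone=, label=)`, nm.
#' @slot backboneIntensity,spotIntensity mean peak photon counts of the
#'   backbone line and of one fluorophore.
#' @slot backgroundLevel mean background photons per pixel.
#' @slot readNoiseSigma Gaussian read noise SD in output counts.
#' @slot emGain multiplicative electron-multiplying gain.
#' @slot seed RNG seed.
#' @export
setClass("SceneSpec", representation(
  imageHeightPx = "integer", imageWidthPx = "integer",
  pixelSizeNm = "numeric", nMolecules = "integer",
  fragmentLengthBpMean = "numeric", fragmentLengthBpSigma = "numeric",
  stretchFactor = "numeric", orientationDegMean = "numeric",
  orientationDegSigma = "numeric",
  markDensity = "numeric", labellingEfficiency = "numeric",
  psfSigmaNm = "numeric", backboneIntensity = "numeric",
  spotIntensity = "numeric", backgroundLevel = "numeric",
  readNoiseSigma = "numeric", emGain = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  chk <- function(expr, m) if (!isTRUE(expr)) msg <<- c(msg, m)
  chk(object@imageHeightPx >= 8L && object@imageWidthPx >= 8L,
      "imageHeightPx/imageWidthPx must be >= 8")
  chk(object@pixelSizeNm > 0, "pixelSizeNm must be > 0")
  chk(object@nMolecules >= 0L, "nMolecules must be >= 0")
  chk(object@fragmentLengthBpMean > 0, "fragmentLengthBpMean must be > 0")
  chk(object@fragmentLengthBpSigma >= 0, "fragmentLengthBpSigma must be >= 0")
  chk(object@stretchFactor > 0 && object@stretchFactor <= 1.1,
      "stretchFactor must lie in (0, 1.1]")
  chk(object@markDensity >= 0 && object@markDensity <= 1,
      "markDensity must lie in [0, 1]")
  chk(object@labellingEfficiency >= 0 && object@labellingEfficiency <= 1,
      "labellingEfficiency must lie in [0, 1]")
  chk(length(object@psfSigmaNm) == 2L && all(object@psfSigmaNm > 0) &&
        all(c("backbone", "label") %in% names(object@psfSigmaNm)),
      "psfSigmaNm must be positive and named c(backbone=, label=)")
  chk(object@backboneIntensity >= 0 && object@spotIntensity >= 0,
      "intensities must be >= 0")
  chk(object@backgroundLevel >= 0 && object@readNoiseSigma >= 0 &&
        object@emGain > 0, "noise/gain parameters out of range")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' Defaults describe a realistic acquisition: 160 nm pixels, a 1024 px
#' square field, ~30 kbp molecules stretched to 0.85 of contour length
#' and nearly aligned with the horizontal axis, EMCCD-like noise.
#'
#' @param imageHeightPx,imageWidthPx field size in pixels.
#' @param pixelSizeNm pixel size in nm.
#' @param nMolecules molecules per field.
#' @param fragmentLengthBpMean,fragmentLengthBpSigma lognormal molecule
#'   length: mean in bp and sdlog.
#' @param stretchFactor extension relative to B-form contour.
#' @param orientationDegMean mean orientation, degrees.
#' @param orientationDegSigma angular jitter SD, degrees.
#' @param markDensity per-base 5hmC probability (fraction of bases).
#' @param labellingEfficiency per-mark fluorophore probability.
#' @param psfSigmaNm named PSF sigmas `c(backbone=, label=)`, nm.
#' @param backboneIntensity,spotIntensity peak photons.
#' @param backgroundLevel background photons per pixel.
#' @param readNoiseSigma read noise SD, output counts.
#' @param emGain EM gain.
#' @param seed RNG seed.
#' @return A validated [SceneSpec-class] object.
#' @examples
#' spec <- sceneSpec(nMolecules = 5L, markDensity = 4.2e-5, seed = 1L)
#' @export
sceneSpec <- function(imageHeightPx = 1024L, imageWidthPx = 1024L,
                      pixelSizeNm = 160, nMolecules = 90L,
                      fragmentLengthBpMean = 30000,
                      fragmentLengthBpSigma = 0.35,
                      stretchFactor = 0.85, orientationDegMean = 0,
                      orientationDegSigma = 5,
                      markDensity = 4.2e-5, labellingEfficiency = 1,
                      psfSigmaNm = c(backbone = 85, label = 130),
                      backboneIntensity = 60, spotIntensity = 80,
                      backgroundLevel = 20, readNoiseSigma = 20,
                      emGain = 30, seed = 1L) {
  new("SceneSpec",
      imageHeightPx = as.integer(imageHeightPx),
      imageWidthPx = as.integer(imageWidthPx),
      pixelSizeNm = as.numeric(pixelSizeNm),
      nMolecules = as.integer(nMolecules),
      fragmentLengthBpMean = as.numeric(fragmentLengthBpMean),
      fragmentLengthBpSigma = as.numeric(fragmentLengthBpSigma),
      stretchFactor = as.numeric(stretchFactor),
      orientationDegMean = as.numeric(orientationDegMean),
      orientationDegSigma = as.numeric(orientationDegSigma),
      markDensity = as.numeric(markDensity),
      labellingEfficiency = as.numeric(labellingEfficiency),
      psfSigmaNm = psfSigmaNm,
      backboneIntensity = as.numeric(backboneIntensity),
      spotIntensity = as.numeric(spotIntensity),
      backgroundLevel = as.numeric(backgroundLevel),
      readNoiseSigma = as.numeric(readNoiseSigma),
      emGain = as.numeric(emGain), seed = as.integer(seed))
}

#' Ground truth of a rendered scene
#'
#' Oracle record written by [renderScene()]: one row per molecule
#' (subpixel endpoints, contour length in bp, rendered length in px,
#' clipping flag), one row per 5hmC mark (bp offset, pixel coordinates,
#' fluorophore flag) and scene totals.
#'
#' @slot molecules data.frame with columns `id, r0, c0, r1, c1,
#'   contourLengthBp, lengthPx, thetaDeg, nMarks, nLabelled, clipped`.
#' @slot marks data.frame with columns `molecule, offsetBp, row, col,
#'   labelled`.
#' @slot totals list: `totalBp`, `totalLengthPx`, `nMarks`, `nLabelled`.
#' @export
setClass("GroundTruth", representation(
  molecules = "data.frame", marks = "data.frame", totals = "list"))

setValidity("GroundTruth", function(object) {
  need <- c("id", "r0", "c0", "r1", "c1", "contourLengthBp", "lengthPx",
            "thetaDeg", "nMarks", "nLabelled", "clipped")
  if (!all(need %in% names(object@molecules)))
    return("molecules table is missing required columns")
  if (nrow(object@marks) &&
      !all(c("molecule", "offsetBp", "row", "col", "labelled") %in%
             names(object@marks)))
    return("marks table is missing required columns")
  tot <- object@totals
  if (!all(c("totalBp", "totalLengthPx", "nMarks", "nLabelled") %in%
             names(tot)))
    return("totals incomplete")
  if (abs(tot$totalBp - sum(object@molecules$contourLengthBp)) > 1e-6 ||
      abs(tot$totalLengthPx - sum(object@molecules$lengthPx)) > 1e-6)
    return("totals do not equal sums over molecules")
  TRUE
})

#' A rendered synthetic scene
#'
#' @slot channels integer array `height x width x 2`; plane 1 is the DNA
#'   backbone channel, plane 2 the 5hmC label channel (16-bit counts).
#' @slot truth the [GroundTruth-class] record.
#' @slot spec the generating [SceneSpec-class].
#' @export
setClass("FiberScene", representation(
  channels = "array", truth = "GroundTruth", spec = "SceneSpec"))

setValidity("FiberScene", function(object) {
  d <- dim(object@channels)
  if (length(d) != 3L || d[3] != 2L)
    return("channels must be a height x width x 2 array")
  TRUE
})

#' Parameters of one simulated photobleaching trace
#'
#' @slot nFluorophores number of fluorophores (downward steps), >= 0.
#' @slot frames trace length in frames.
#' @slot bleachTimeMeanFrames mean of the (truncated) exponential bleach
#'   time per fluorophore, frames.
#' @slot stepHeight intensity lost when one fluorophore bleaches.
#' @slot background final mean level after all fluorophores bleach.
#' @slot noiseSigma additive Gaussian noise SD; SNR = stepHeight/noiseSigma.
#' @slot seed RNG seed.
#' @export
setClass("BleachTraceSpec", representation(
  nFluorophores = "integer", frames = "integer",
  bleachTimeMeanFrames = "numeric", stepHeight = "numeric",
  background = "numeric", noiseSigma = "numeric", seed = "integer"))

setValidity("BleachTraceSpec", function(object) {
  if (object@nFluorophores < 0L) return("nFluorophores must be >= 0")
  if (object@frames < object@nFluorophores + 2L)
    return("frames too few to hold the requested number of steps")
  if (object@bleachTimeMeanFrames <= 0) return("bleachTimeMeanFrames must be > 0")
  if (object@stepHeight <= 0) return("stepHeight must be > 0")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' Construct a BleachTraceSpec
#'
#' @param nFluorophores fluorophore count (true number of steps).
#' @param frames trace length.
#' @param bleachTimeMeanFrames mean bleach time, frames.
#' @param stepHeight per-fluorophore intensity step.
#' @param background final level.
#' @param noiseSigma Gaussian noise SD.
#' @param seed RNG seed.
#' @return A validated [BleachTraceSpec-class].
#' @examples
#' bleachTraceSpec(nFluorophores = 2L, noiseSigma = 20, seed = 7L)
#' @export
bleachTraceSpec <- function(nFluorophores = 1L, frames = 200L,
                            bleachTimeMeanFrames = 60, stepHeight = 100,
                            background = 50, noiseSigma = 20, seed = 1L) {
  new("BleachTraceSpec", nFluorophores = as.integer(nFluorophores),
      frames = as.integer(frames),
      bleachTimeMeanFrames = as.numeric(bleachTimeMeanFrames),
      stepHeight = as.numeric(stepHeight),
      background = as.numeric(background),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' A traced DNA molecule backbone
#'
#' One-pixel-wide 8-connected path from one molecule endpoint to the
#' other, with its geometric length (axial steps cost 1, diagonal steps
#' sqrt(2)).
#'
#' @slot id molecule identifier within an image.
#' @slot path integer matrix (n x 2, columns row/col), ordered
#'   endpoint-to-endpoint, no repeated pixel.
#' @slot lengthPx geometric path length in pixels.
#' @slot meanIntensity mean backbone-channel intensity along the path.
#' @slot flags character vector of QC flags (empty for retained traces).
#' @export
setClass("MoleculeTrace", representation(
  id = "integer", path = "matrix", lengthPx = "numeric",
  meanIntensity = "numeric", flags = "character"))

setValidity("MoleculeTrace", function(object) {
  p <- object@path
  if (ncol(p) != 2L) return("path must have two columns (row, col)")
  if (nrow(p) >= 2L) {
    st <- abs(diff(p))
    if (any(st > 1L) || any(rowSums(st) == 0L))
      return("path must be 8-connected with no repeated pixel")
    if (anyDuplicated(paste(p[, 1], p[, 2], sep = ",")))
      return("path must be simple (no repeated pixel)")
  }
  TRUE
})

#' A molecule with its assigned 5hmC spots
#'
#' @slot trace the [MoleculeTrace-class].
#' @slot spots data.frame of assigned spots (subset of the detection
#'   table, plus `distancePx`).
#' @slot nSpots number of assigned spots.
#' @export
setClass("LabeledMolecule", representation(
  trace = "MoleculeTrace", spots = "data.frame", nSpots = "integer"))

setValidity("LabeledMolecule", function(object) {
  if (object@nSpots != nrow(object@spots))
    return("nSpots must equal the number of assigned spots")
  TRUE
})

#' Piecewise-constant fit of a photobleaching trace
#'
#' @slot changePoints integer indices i such that a new segment starts at
#'   frame i + 1 (empty for a constant fit).
#' @slot levels fitted mean per segment, in trace order.
#' @slot stepCount number of change points whose level decreases.
#' @slot score penalized cost (RSS + penalty x changepoints x log n).
#' @export
setClass("StepFit", representation(
  changePoints = "integer", levels = "numeric", stepCount = "integer",
  score = "numeric"))

setValidity("StepFit", function(object) {
  if (length(object@levels) != length(object@changePoints) + 1L)
    return("levels must have one more entry than changePoints")
  if (object@stepCount < 0L || object@stepCount > length(object@changePoints))
    return("stepCount out of range")
  TRUE
})

#' Distribution of fluorophores per resolvable 5hmC site
#'
#' `p[k]` is the probability that a diffraction-limited site carries `k`
#' fluorophores; its mean is the cluster-correction factor applied during
#' calibration.
#'
#' @slot p numeric probabilities for k = 1..Kmax, summing to 1.
#' @slot nTraces number of traces the distribution was estimated from.
#' @export
setClass("ClusterDist", representation(p = "numeric", nTraces = "integer"))

setValidity("ClusterDist", function(object) {
  if (any(object@p < 0) || abs(sum(object@p) - 1) > 1e-8)
    return("p must be non-negative and sum to 1")
  TRUE
})

#' Constants converting raw spot density into %5hmC/dNTPs
#'
#' Holds the labelling efficiency, DNA stretch factor, pixel geometry,
#' cluster correction and (optionally) a side-by-side reference standard
#' used for between-experiment normalization.
#'
#' @slot labellingEfficiency probability a 5hmC mark is labelled, (0, 1].
#' @slot stretchFactor DNA extension relative to B-form contour, > 0.
#' @slot pixelSizeNm pixel size, nm.
#' @slot clusterCorrection mean fluorophores per resolvable site, >= 1.
#' @slot referenceKnownPercent known %5hmC of the calibration standard
#'   (NA when unused).
#' @slot referenceMeasuredDensity measured raw density (spots/px) of the
#'   standard in the same experiment (NA when unused).
#' @export
setClass("CalibrationModel", representation(
  labellingEfficiency = "numeric", stretchFactor = "numeric",
  pixelSizeNm = "numeric", clusterCorrection = "numeric",
  referenceKnownPercent = "numeric", referenceMeasuredDensity = "numeric"))

setValidity("CalibrationModel", function(object) {
  if (object@labellingEfficiency <= 0 || object@labellingEfficiency > 1)
    return("labellingEfficiency must lie in (0, 1]")
  if (object@stretchFactor <= 0) return("stretchFactor must be > 0")
  if (object@pixelSizeNm <= 0) return("pixelSizeNm must be > 0")
  if (object@clusterCorrection < 1) return("clusterCorrection must be >= 1")
  ref.set <- !is.na(object@referenceKnownPercent) +
    !is.na(object@referenceMeasuredDensity)
  if (ref.set == 1L)
    return("referenceKnownPercent and referenceMeasuredDensity must be set together")
  if (!is.na(object@referenceMeasuredDensity) &&
      object@referenceMeasuredDensity <= 0)
    return("referenceMeasuredDensity must be > 0")
  TRUE
})

#' Construct a CalibrationModel
#'
#' @param labellingEfficiency fluorophore labelling efficiency, (0, 1].
#' @param stretchFactor DNA stretch factor.
#' @param pixelSizeNm pixel size, nm.
#' @param clusterCorrection mean fluorophores per resolvable site.
#' @param referenceKnownPercent,referenceMeasuredDensity optional
#'   side-by-side standard: its known %5hmC and its measured raw density.
#' @return A validated [CalibrationModel-class].
#' @examples
#' calibrationModel(labellingEfficiency = 0.8, stretchFactor = 0.85)
#' @export
calibrationModel <- function(labellingEfficiency = 1, stretchFactor = 0.85,
                             pixelSizeNm = 160, clusterCorrection = 1,
                             referenceKnownPercent = NA_real_,
                             referenceMeasuredDensity = NA_real_) {
  new("CalibrationModel",
      labellingEfficiency = as.numeric(labellingEfficiency),
      stretchFactor = as.numeric(stretchFactor),
      pixelSizeNm = as.numeric(pixelSizeNm),
      clusterCorrection = as.numeric(clusterCorrection),
      referenceKnownPercent = as.numeric(referenceKnownPercent),
      referenceMeasuredDensity = as.numeric(referenceMeasuredDensity))
}

#' Running-density convergence curve
#'
#' One point per molecule in acquisition order: cumulative DNA length
#' versus cumulative spots / cumulative length. A plateau of the curve
#' indicates that enough DNA was sampled for a stable estimate.
#'
#' @slot points data.frame `cumLengthPx, cumSpots, density`.
#' @slot moleculeOrder order in which molecules were accumulated.
#' @slot converged TRUE when the trailing window stays within the plateau
#'   tolerance of the final density.
#' @slot tolerance relative plateau tolerance used.
#' @slot tailFraction trailing fraction of cumulative length checked.
#' @export
setClass("ConvergenceCurve", representation(
  points = "data.frame", moleculeOrder = "integer", converged = "logical",
  tolerance = "numeric", tailFraction = "numeric"))

setValidity("ConvergenceCurve", function(object) {
  cl <- object@points$cumLengthPx
  if (length(cl) > 1L && any(diff(cl) <= 0))
    return("cumulative length must be strictly increasing")
  TRUE
})

#' Per-sample quantification result
#'
#' @slot perMolecule data.frame: one row per retained molecule
#'   (`scene, molecule, lengthPx, nSpots, meanIntensity`).
#' @slot totals list: `totalLengthPx`, `totalSpots`, `nMolecules`,
#'   `nOrphans`.
#' @slot rawDensity spots per pixel of DNA (NA for an empty sample).
#' @slot percent5hmC calibrated %5hmC/dNTPs (NA without calibration).
#' @slot convergence the [ConvergenceCurve-class] (may be empty).
#' @slot splitHalf list from [splitHalfSD()] (may be empty).
#' @slot calibration the [CalibrationModel-class] used (may be NULL).
#' @slot seed run seed recorded for reproducibility.
#' @export
setClass("SampleResult", representation(
  perMolecule = "data.frame", totals = "list", rawDensity = "numeric",
  percent5hmC = "numeric", convergence = "ANY", splitHalf = "list",
  calibration = "ANY", seed = "integer"))

setValidity("SampleResult", function(object) {
  tot <- object@totals
  if (!all(c("totalLengthPx", "totalSpots", "nMolecules") %in% names(tot)))
    return("totals incomplete")
  if (nrow(object@perMolecule)) {
    if (abs(tot$totalLengthPx - sum(object@perMolecule$lengthPx)) > 1e-6 ||
        tot$totalSpots != sum(object@perMolecule$nSpots))
      return("totals do not equal column sums")
  }
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px (%g nm/px), %d molecules\n",
              object@imageHeightPx, object@imageWidthPx,
              object@pixelSizeNm, object@nMolecules))
  cat(sprintf("  fragments ~ %g bp (sdlog %g), stretch %g, mark density %g\n",
              object@fragmentLengthBpMean, object@fragmentLengthBpSigma,
              object@stretchFactor, object@markDensity))
  cat(sprintf("  labelling efficiency %g, seed %d\n",
              object@labellingEfficiency, object@seed))
})

setMethod("show", "FiberScene", function(object) {
  d <- dim(object@channels)
  cat(sprintf("FiberScene: %d x %d px, 2 channels; %d molecules, %d marks (%d labelled)\n",
              d[1], d[2], nrow(object@truth@molecules),
              object@truth@totals$nMarks, object@truth@totals$nLabelled))
})

setMethod("show", "MoleculeTrace", function(object) {
  cat(sprintf("MoleculeTrace %d: %d px path, length %.2f px%s\n",
              object@id, nrow(object@path), object@lengthPx,
              if (length(object@flags)) paste0(" [",
                paste(object@flags, collapse = ","), "]") else ""))
})

setMethod("show", "StepFit", function(object) {
  cat(sprintf("StepFit: %d segment(s), %d downward step(s), score %.3g\n",
              length(object@levels), object@stepCount, object@score))
})

setMethod("show", "ClusterDist", function(object) {
  cat(sprintf("ClusterDist over %d traces; mean cluster size %.3f\n",
              object@nTraces, sum(seq_along(object@p) * object@p)))
  print(round(object@p, 4))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel: eps %g, stretch %g, %g nm/px (%.1f bp/px), C %g%s\n",
    object@labellingEfficiency, object@stretchFactor, object@pixelSizeNm,
    bpPerPx(object), object@clusterCorrection,
    if (!is.na(object@referenceKnownPercent))
      sprintf(", reference %g%%", object@referenceKnownPercent) else ""))
})

setMethod("show", "SampleResult", function(object) {
  cat(sprintf("SampleResult: %d molecules, %.0f px DNA, %d spots\n",
              object@totals$nMolecules, object@totals$totalLengthPx,
              object@totals$totalSpots))
  cat(sprintf("  raw density %.4g spots/px; %%5hmC/dNTPs %.4g\n",
              object@rawDensity, object@percent5hmC))
  if (length(object@splitHalf))
    cat(sprintf("  split-half relative SD %.2f%%; converged: %s\n",
                object@splitHalf$relativeSD,
                if (is(object@convergence, "ConvergenceCurve"))
                  object@convergence@converged else NA))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for fiberHMC objects
#'
#' Small read-only accessors so downstream code never touches slots
#' directly.
#'
#' @param x object to access.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
sceneChannels <- function(x) { stopifnot(is(x, "FiberScene")); x@channels }

#' @rdname accessors
#' @export
sceneTruth <- function(x) { stopifnot(is(x, "FiberScene")); x@truth }

#' @rdname accessors
#' @export
sceneSpecOf <- function(x) { stopifnot(is(x, "FiberScene")); x@spec }

#' @rdname accessors
#' @export
tracePath <- function(x) { stopifnot(is(x, "MoleculeTrace")); x@path }

#' @rdname accessors
#' @export
traceFlags <- function(x) { stopifnot(is(x, "MoleculeTrace")); x@flags }

#' @rdname accessors
#' @export
stepCount <- function(x) { stopifnot(is(x, "StepFit")); x@stepCount }

#' @rdname accessors
#' @export
stepLevels <- function(x) { stopifnot(is(x, "StepFit")); x@levels }

#' @rdname accessors
#' @export
changePoints <- function(x) { stopifnot(is(x, "StepFit")); x@changePoints }

#' @rdname accessors
#' @export
clusterProbs <- function(x) { stopifnot(is(x, "ClusterDist")); x@p }

#' Bases of DNA per image pixel
#'
#' `bp/px = pixelSizeNm / (0.34 nm/bp * stretchFactor)`: how many bases
#' of stretched DNA one pixel of traced backbone represents.
#'
#' @param model a [CalibrationModel-class].
#' @return Bases per pixel.
#' @examples
#' bpPerPx(calibrationModel())  # 160 / (0.34 * 0.85) = 553.6
#' @export
bpPerPx <- function(model) {
  stopifnot(is(model, "CalibrationModel"))
  model@pixelSizeNm / (.BP_NM * model@stretchFactor)
}

#' @rdname accessors
#' @export
sampleTotals <- function(x) { stopifnot(is(x, "SampleResult")); x@totals }

#' @rdname accessors
#' @export
samplePerMolecule <- function(x) { stopifnot(is(x, "SampleResult")); x@perMolecule }

#' @rdname accessors
#' @export
sampleDensity <- function(x) { stopifnot(is(x, "SampleResult")); x@rawDensity }

#' @rdname accessors
#' @export
samplePercent <- function(x) { stopifnot(is(x, "SampleResult")); x@percent5hmC }

#' @rdname accessors
#' @export
sampleSplitHalf <- function(x) { stopifnot(is(x, "SampleResult")); x@splitHalf }

#' @rdname accessors
#' @export
sampleConvergence <- function(x) { stopifnot(is(x, "SampleResult")); x@convergence }
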