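## On-disk artifacts: YAML run configuration, multi-page TIFF scenes,
## CSV/JSON results and bleach-trace tables. All randomness in a run
## flows from the single seed recorded in the summary JSON.

#' Run configuration
#'
#' Validated container for everything a quantification run needs:
#' pixel geometry, channel assignment, per-module detection parameter
#' blocks, calibration constants and the run seed.
#'
#' @slot pixelSizeNm pixel size, nm.
#' @slot channels integer `c(backbone=, label=)` TIFF page numbers
#'   (1-based).
#' @slot backbone,spots,colocal,convergence,splitHalf parameter lists
#'   (see [backboneParams()], [spotParams()], [assignSpots()],
#'   [convergenceCurve()], [splitHalfSD()]).
#' @slot calibration a [CalibrationModel-class].
#' @slot seed run seed.
#' @export
setClass("RunConfig", representation(
  pixelSizeNm = "numeric", channels = "integer", backbone = "list",
  spots = "list", colocal = "list", convergence = "list",
  splitHalf = "list", calibration = "CalibrationModel", seed = "integer"))

setValidity("RunConfig", function(object) {
  if (object@pixelSizeNm <= 0) return("pixelSizeNm must be > 0")
  if (length(object@channels) != 2L || any(object@channels < 1L) ||
      !all(c("backbone", "label") %in% names(object@channels)))
    return("channels must be positive pages named c(backbone=, label=)")
  TRUE
})

#' Construct a RunConfig
#'
#' Unknown parameter names and out-of-range values are rejected with the
#' offending field named.
#'
#' @param pixelSizeNm pixel size in nm.
#' @param channels TIFF pages of the two channels (1-based).
#' @param backbone,spots,colocal,convergence,splitHalf named parameter
#'   overrides for the respective stages.
#' @param calibration a [CalibrationModel-class].
#' @param seed run seed (all shuffling derives from it).
#' @return A validated [RunConfig-class].
#' @examples
#' cfg <- runConfig(spots = list(thresholdK = 6))
#' @export
runConfig <- function(pixelSizeNm = 160,
                      channels = c(backbone = 1L, label = 2L),
                      backbone = list(), spots = list(), colocal = list(),
                      convergence = list(), splitHalf = list(),
                      calibration = calibrationModel(pixelSizeNm = pixelSizeNm),
                      seed = 1L) {
  checkBlock <- function(block, allowed, name) {
    if (!is.list(block)) failField(name, "must be a named list")
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      failField(paste(name, bad[1], sep = "."), "unknown parameter")
    block
  }
  backbone <- checkBlock(backbone, names(backboneParams()), "backbone")
  spots <- checkBlock(spots, names(spotParams()), "spots")
  colocal <- checkBlock(colocal, c("maxDistPx", "offsetPx"), "colocal")
  convergence <- checkBlock(convergence, c("tolerance", "tailFraction"),
                            "convergence")
  splitHalf <- checkBlock(splitHalf, c("balanceTol"), "splitHalf")
  if (!is.null(colocal$maxDistPx))
    checkRange(colocal$maxDistPx, "colocal.maxDistPx", lo = 0, lo.open = TRUE)
  if (!is.null(spots$thresholdK))
    checkRange(spots$thresholdK, "spots.thresholdK", lo = 0, lo.open = TRUE)
  if (!is.null(backbone$minLengthPx))
    checkRange(backbone$minLengthPx, "backbone.minLengthPx", lo = 0)
  checkRange(pixelSizeNm, "pixelSizeNm", lo = 0, lo.open = TRUE)
  new("RunConfig", pixelSizeNm = as.numeric(pixelSizeNm),
      channels = setNames(as.integer(channels),
                          names(channels)),
      backbone = backbone, spots = spots, colocal = colocal,
      convergence = convergence, splitHalf = splitHalf,
      calibration = calibration, seed = as.integer(seed))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any of the fields of [runConfig()];
#'   `calibration` is a block with the fields of [calibrationModel()].
#' @return A validated [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("pixel_size_nm", "channels", "backbone", "spots", "colocal",
             "convergence", "split_half", "calibration", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) failField(bad[1], "unknown configuration field")
  cal <- if (!is.null(y$calibration)) {
    do.call(calibrationModel, modifyList(
      list(pixelSizeNm = y$pixel_size_nm %||% 160), y$calibration))
  } else {
    calibrationModel(pixelSizeNm = y$pixel_size_nm %||% 160)
  }
  ch <- if (!is.null(y$channels)) {
    c(backbone = as.integer(y$channels$backbone),
      label = as.integer(y$channels$label))
  } else {
    c(backbone = 1L, label = 2L)
  }
  runConfig(pixelSizeNm = y$pixel_size_nm %||% 160, channels = ch,
            backbone = y$backbone %||% list(), spots = y$spots %||% list(),
            colocal = y$colocal %||% list(),
            convergence = y$convergence %||% list(),
            splitHalf = y$split_half %||% list(),
            calibration = cal, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scene as a 2-page 16-bit TIFF
#'
#' Page 1 holds the backbone channel, page 2 the label channel. Values
#' must be integer counts in [0, 65535]; they round-trip bit-identically
#' through [readScene()].
#'
#' @param scene a [FiberScene-class] or a `h x w x 2` array.
#' @param path output file.
#' @param truthPath optional path for the ground-truth JSON sidecar
#'   (only for a [FiberScene-class]).
#' @return `path`, invisibly.
#' @export
writeScene <- function(scene, path, truthPath = NULL) {
  arr <- if (is(scene, "FiberScene")) sceneChannels(scene) else scene
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] == 2L)
  pages <- lapply(1:2, function(k) arr[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  if (!is.null(truthPath) && is(scene, "FiberScene"))
    writeGroundTruth(sceneTruth(scene), truthPath)
  invisible(path)
}

#' Read a two-channel scene from a multi-page TIFF
#'
#' @param path TIFF file.
#' @param pages 1-based page numbers of the (backbone, label) channels.
#' @return Integer array `h x w x 2` of camera counts.
#' @export
readScene <- function(path, pages = c(1L, 2L)) {
  if (!file.exists(path)) stop("scene file not found: ", path)
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                   error = function(e)
                     stop("unreadable TIFF: ", path, call. = FALSE))
  if (!is.list(imgs)) imgs <- list(imgs)
  if (length(imgs) < max(pages))
    stop(sprintf("format error: %s has %d page(s), need page(s) %s",
                 path, length(imgs), paste(pages, collapse = ",")))
  ch <- lapply(imgs[pages], function(m) {
    storage.mode(m) <- "integer"
    m
  })
  array(c(ch[[1]], ch[[2]]), c(dim(ch[[1]]), 2L))
}

#' Write/read a ground-truth record
#'
#' JSON sidecar of a rendered scene: molecule table, mark table, totals.
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON file.
#' @return `path` invisibly / the re-read [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  jsonlite::write_json(
    list(molecules = truth@molecules, marks = truth@marks,
         totals = truth@totals),
    path, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mol <- as.data.frame(j$molecules)
  marks <- as.data.frame(j$marks)
  if (!nrow(marks))
    marks <- data.frame(molecule = integer(), offsetBp = numeric(),
                        row = numeric(), col = numeric(),
                        labelled = logical())
  new("GroundTruth", molecules = mol, marks = marks, totals = j$totals)
}

#' Write and read bleach traces as long-format CSV
#'
#' Columns `trace`, `frame`, `intensity`; one block of rows per trace.
#'
#' @param traces list of numeric intensity vectors.
#' @param path CSV file.
#' @return `path` invisibly / a named list of numeric vectors.
#' @export
writeBleachTraces <- function(traces, path) {
  stopifnot(is.list(traces))
  if (is.null(names(traces))) names(traces) <- seq_along(traces)
  df <- do.call(rbind, lapply(names(traces), function(id)
    data.frame(trace = id, frame = seq_along(traces[[id]]),
               intensity = traces[[id]])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBleachTraces
#' @export
readBleachTraces <- function(path) {
  df <- read.csv(path)
  need <- c("trace", "frame", "intensity")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns trace, frame, intensity")
  out <- lapply(split(df, df$trace), function(d)
    d$intensity[order(d$frame)])
  out[unique(as.character(df$trace))]
}

#' Write a sample result to disk
#'
#' Produces `molecules.csv` (per-molecule table), `summary.json`
#' (totals, densities, QC and calibration constants) and
#' `convergence.csv` (running-density curve). An empty sample is written
#' with zero totals and a null density flag. Re-reading with
#' [readResults()] reproduces totals exactly.
#'
#' @param result a [SampleResult-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeResults <- function(result, dir) {
  stopifnot(is(result, "SampleResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result@perMolecule, file.path(dir, "molecules.csv"),
            row.names = FALSE)
  conv <- if (is(result@convergence, "ConvergenceCurve"))
    result@convergence@points else
      data.frame(cumLengthPx = numeric(), cumSpots = numeric(),
                 density = numeric())
  write.csv(conv, file.path(dir, "convergence.csv"), row.names = FALSE)
  cal <- result@calibration
  summary <- list(
    totals = result@totals,
    rawDensity = if (is.na(result@rawDensity)) NULL else result@rawDensity,
    densityDefined = !is.na(result@rawDensity),
    percent5hmC = if (is.na(result@percent5hmC)) NULL else
      result@percent5hmC,
    splitHalf = result@splitHalf,
    converged = if (is(result@convergence, "ConvergenceCurve"))
      result@convergence@converged else NA,
    calibration = if (is(cal, "CalibrationModel")) list(
      labellingEfficiency = cal@labellingEfficiency,
      stretchFactor = cal@stretchFactor, pixelSizeNm = cal@pixelSizeNm,
      clusterCorrection = cal@clusterCorrection,
      referenceKnownPercent = cal@referenceKnownPercent,
      referenceMeasuredDensity = cal@referenceMeasuredDensity) else NULL,
    seed = result@seed)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(dir)
}

#' Read back a sample result
#'
#' @param dir directory written by [writeResults()].
#' @return A [SampleResult-class].
#' @export
readResults <- function(dir) {
  mol <- read.csv(file.path(dir, "molecules.csv"))
  s <- jsonlite::read_json(file.path(dir, "summary.json"),
                           simplifyVector = TRUE)
  conv.df <- read.csv(file.path(dir, "convergence.csv"))
  conv <- if (nrow(conv.df)) {
    new("ConvergenceCurve", points = conv.df,
        moleculeOrder = seq_len(nrow(conv.df)),
        converged = isTRUE(s$converged), tolerance = 0.05,
        tailFraction = 0.2)
  } else {
    NULL
  }
  cal <- if (!is.null(s$calibration)) {
    do.call(calibrationModel, lapply(s$calibration, function(v)
      if (is.null(v)) NA_real_ else v))
  } else {
    NULL
  }
  new("SampleResult", perMolecule = mol,
      totals = s$totals,
      rawDensity = if (isTRUE(s$densityDefined)) s$rawDensity else NA_real_,
      percent5hmC = if (!is.null(s$percent5hmC)) s$percent5hmC else NA_real_,
      convergence = conv, splitHalf = as.list(s$splitHalf),
      calibration = cal, seed = as.integer(s$seed))
}
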