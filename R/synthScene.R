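## Synthetic-scene simulator: stretched DNA molecules with Bernoulli 5hmC
## marks rendered through a Gaussian PSF onto an EMCCD-like camera, plus
## stepwise photobleaching traces. Every scene carries its ground truth.

## Analytic image of a finite line segment convolved with a 2-D Gaussian:
## for a point at perpendicular distance d and longitudinal coordinate t
## along a segment of length L, intensity = A * exp(-d^2 / 2s^2) *
## (pnorm((L - t)/s) - pnorm(-t/s)); peak A in the middle of a long line.
addSegment <- function(img, p0, p1, sigmaPx, amp) {
  if (amp <= 0) return(img)
  h <- nrow(img); w <- ncol(img)
  len <- sqrt(sum((p1 - p0)^2))
  pad <- ceiling(4 * sigmaPx)
  rs <- max(1L, floor(min(p0[1], p1[1]) - pad)):min(h, ceiling(max(p0[1], p1[1]) + pad))
  cs <- max(1L, floor(min(p0[2], p1[2]) - pad)):min(w, ceiling(max(p0[2], p1[2]) + pad))
  if (!length(rs) || !length(cs)) return(img)
  if (len < 1e-9) return(addEmitter(img, p0, sigmaPx, amp))
  u <- (p1 - p0) / len
  rr <- matrix(rs, length(rs), length(cs))
  cc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  wr <- rr - p0[1]; wc <- cc - p0[2]
  t <- wr * u[1] + wc * u[2]
  d2 <- (wr - t * u[1])^2 + (wc - t * u[2])^2
  val <- amp * exp(-d2 / (2 * sigmaPx^2)) *
    (pnorm((len - t) / sigmaPx) - pnorm(-t / sigmaPx))
  img[rs, cs] <- img[rs, cs] + val
  img
}

addEmitter <- function(img, p, sigmaPx, amp) {
  h <- nrow(img); w <- ncol(img)
  pad <- ceiling(5 * sigmaPx)
  rs <- max(1L, floor(p[1] - pad)):min(h, ceiling(p[1] + pad))
  cs <- max(1L, floor(p[2] - pad)):min(w, ceiling(p[2] + pad))
  if (!length(rs) || !length(cs)) return(img)
  gr <- exp(-(rs - p[1])^2 / (2 * sigmaPx^2))
  gc <- exp(-(cs - p[2])^2 / (2 * sigmaPx^2))
  img[rs, cs] <- img[rs, cs] + amp * outer(gr, gc)
  img
}

#' Render an ideal image of point emitters
#'
#' Noise-free Gaussian-PSF image of fluorophores at given subpixel
#' positions. Used internally for the label channel of [renderScene()]
#' and directly useful for controlled detection experiments (e.g. two
#' emitters below the diffraction limit).
#'
#' @param centers numeric matrix (n x 2) of subpixel (row, col) positions.
#' @param dim image dimensions `c(height, width)`.
#' @param sigmaPx PSF sigma in pixels.
#' @param amplitude peak intensity per emitter (recycled).
#' @return A numeric matrix.
#' @examples
#' img <- renderEmitters(rbind(c(16, 14), c(16, 18)), c(32, 32), 1.2, 100)
#' @export
renderEmitters <- function(centers, dim, sigmaPx, amplitude = 1) {
  stopifnot(is.matrix(centers) || length(centers) == 2L, sigmaPx > 0)
  if (!is.matrix(centers)) centers <- matrix(centers, 1L)
  img <- matrix(0, dim[1], dim[2])
  amplitude <- rep_len(amplitude, nrow(centers))
  for (i in seq_len(nrow(centers)))
    img <- addEmitter(img, centers[i, ], sigmaPx, amplitude[i])
  img
}

#' Render an ideal image of line segments
#'
#' Noise-free image of straight DNA backbones at explicit subpixel
#' endpoints, each a finite line convolved with a Gaussian PSF. Useful
#' for controlled tracing experiments (e.g. deliberately crossing
#' molecules) where [renderScene()]'s random placement is too coarse.
#'
#' @param endpoints numeric matrix (n x 4) with columns `r0, c0, r1, c1`.
#' @param dim image dimensions `c(height, width)`.
#' @param sigmaPx PSF sigma in pixels.
#' @param amplitude peak intensity per segment (recycled).
#' @return A numeric matrix.
#' @examples
#' img <- renderSegments(rbind(c(10, 5, 50, 55), c(50, 5, 10, 55)),
#'                       c(60, 60), 0.6, 60)
#' @export
renderSegments <- function(endpoints, dim, sigmaPx, amplitude = 1) {
  stopifnot(sigmaPx > 0)
  if (!is.matrix(endpoints)) endpoints <- matrix(endpoints, 1L)
  stopifnot(ncol(endpoints) == 4L)
  img <- matrix(0, dim[1], dim[2])
  amplitude <- rep_len(amplitude, nrow(endpoints))
  for (i in seq_len(nrow(endpoints)))
    img <- addSegment(img, endpoints[i, 1:2], endpoints[i, 3:4],
                      sigmaPx, amplitude[i])
  img
}

#' Apply the EMCCD-like camera model
#'
#' Poisson shot noise on (signal + background) photons, multiplied by the
#' EM gain, plus Gaussian read noise; clamped to the 16-bit range. The
#' excess-noise factor of real EM registers is not modelled.
#'
#' @param photons matrix of expected photons per pixel (signal only).
#' @param background mean background photons per pixel.
#' @param emGain multiplicative gain.
#' @param readNoiseSigma Gaussian read noise SD in output counts.
#' @return Integer matrix of camera counts in [0, 65535].
#' @examples
#' set.seed(1); cameraNoise(matrix(5, 8, 8), 20, 30, 20)
#' @export
cameraNoise <- function(photons, background, emGain, readNoiseSigma) {
  n <- length(photons)
  counts <- rpois(n, lambda = as.vector(photons) + background) * emGain +
    rnorm(n, 0, readNoiseSigma)
  matrix(pmin(65535L, pmax(0L, as.integer(round(counts)))),
         nrow(photons), ncol(photons))
}

## Clip the segment p0 -> p1 (subpixel) to the box [lo, hi] in both
## coordinates; returns the clipped endpoints and the retained parameter
## interval [t0, t1] of the original segment.
clipSegment <- function(p0, p1, lo, hi) {
  t0 <- 0; t1 <- 1
  d <- p1 - p0
  for (k in 1:2) {
    if (abs(d[k]) < 1e-12) {
      if (p0[k] < lo[k] || p0[k] > hi[k]) return(NULL)
    } else {
      ta <- (lo[k] - p0[k]) / d[k]; tb <- (hi[k] - p0[k]) / d[k]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) return(NULL)
  list(p0 = p0 + t0 * d, p1 = p0 + t1 * d, t0 = t0, t1 = t1)
}

#' Render a two-channel synthetic scene of stretched DNA molecules
#'
#' Molecules are straight segments (combed DNA is near-linear) with small
#' angular jitter around the horizontal stretching axis; lengths are
#' lognormal in bp; each base carries a 5hmC mark with probability
#' `markDensity`, and each mark a fluorophore with probability
#' `labellingEfficiency`. Channel 1 receives the blurred backbone lines,
#' channel 2 blurred point emitters at labelled mark positions; both pass
#' through the camera model of [cameraNoise()]. Molecules whose segment
#' would leave the field are resampled up to 100 times, then clipped with
#' the truth recording the clipped contour length. Identical specs yield
#' bit-identical scenes.
#'
#' @param spec a [SceneSpec-class].
#' @return A [FiberScene-class] holding the `height x width x 2` count
#'   array, the [GroundTruth-class] record and the spec.
#' @examples
#' sc <- renderScene(sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
#'                             nMolecules = 4L, seed = 7L))
#' sceneTruth(sc)@totals
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    h <- spec@imageHeightPx; w <- spec@imageWidthPx
    nmPerBp <- .BP_NM * spec@stretchFactor
    pxPerBp <- nmPerBp / spec@pixelSizeNm
    sigB <- spec@psfSigmaNm[["backbone"]] / spec@pixelSizeNm
    sigL <- spec@psfSigmaNm[["label"]] / spec@pixelSizeNm
    pad <- 4  # keep blur tails inside the field
    lo <- c(1 + pad, 1 + pad); hi <- c(h - pad, w - pad)
    meanlog <- log(spec@fragmentLengthBpMean) - spec@fragmentLengthBpSigma^2 / 2

    ch1 <- matrix(0, h, w); ch2 <- matrix(0, h, w)
    mols <- vector("list", spec@nMolecules)
    marks <- vector("list", spec@nMolecules)
    for (i in seq_len(spec@nMolecules)) {
      bp <- max(1, round(rlnorm(1, meanlog, spec@fragmentLengthBpSigma)))
      lenPx <- bp * pxPerBp
      theta <- rnorm(1, spec@orientationDegMean,
                     spec@orientationDegSigma) * pi / 180
      dir <- c(sin(theta), cos(theta))
      clipped <- FALSE
      p0 <- p1 <- NULL
      for (attempt in 1:100) {
        ctr <- c(runif(1, 1, h), runif(1, 1, w))
        a <- ctr - dir * lenPx / 2; b <- ctr + dir * lenPx / 2
        if (all(a >= lo & a <= hi) && all(b >= lo & b <= hi)) {
          p0 <- a; p1 <- b
          break
        }
      }
      if (is.null(p0)) {  # clip the last attempt; truth keeps clipped length
        cl <- clipSegment(a, b, lo, hi)
        if (is.null(cl)) { # degenerate (segment misses the box entirely)
          p0 <- p1 <- pmin(pmax(ctr, lo), hi)
          bp <- 1L
        } else {
          p0 <- cl$p0; p1 <- cl$p1
          bp <- max(1L, round(bp * (cl$t1 - cl$t0)))
        }
        lenPx <- bp * pxPerBp
        clipped <- TRUE
      }
      nMarks <- rbinom(1, bp, spec@markDensity)
      if (nMarks > 0) {
        off <- sort(runif(nMarks, 0, bp))
        lab <- runif(nMarks) < spec@labellingEfficiency
        frac <- off / bp
        mr <- p0[1] + frac * (p1[1] - p0[1])
        mc <- p0[2] + frac * (p1[2] - p0[2])
        marks[[i]] <- data.frame(molecule = i, offsetBp = off,
                                 row = mr, col = mc, labelled = lab)
      } else {
        lab <- logical(0)
      }
      mols[[i]] <- data.frame(
        id = i, r0 = p0[1], c0 = p0[2], r1 = p1[1], c1 = p1[2],
        contourLengthBp = bp, lengthPx = lenPx,
        thetaDeg = theta * 180 / pi, nMarks = nMarks,
        nLabelled = sum(lab), clipped = clipped)
      ch1 <- addSegment(ch1, p0, p1, sigB, spec@backboneIntensity)
    }
    molDf <- if (spec@nMolecules) do.call(rbind, mols) else
      data.frame(id = integer(), r0 = numeric(), c0 = numeric(),
                 r1 = numeric(), c1 = numeric(),
                 contourLengthBp = numeric(), lengthPx = numeric(),
                 thetaDeg = numeric(), nMarks = integer(),
                 nLabelled = integer(), clipped = logical())
    markDf <- do.call(rbind, marks[!vapply(marks, is.null, logical(1))])
    if (is.null(markDf))
      markDf <- data.frame(molecule = integer(), offsetBp = numeric(),
                           row = numeric(), col = numeric(),
                           labelled = logical())
    labDf <- markDf[markDf$labelled, , drop = FALSE]
    for (j in seq_len(nrow(labDf)))
      ch2 <- addEmitter(ch2, c(labDf$row[j], labDf$col[j]), sigL,
                        spec@spotIntensity)
    ch1 <- cameraNoise(ch1, spec@backgroundLevel, spec@emGain,
                       spec@readNoiseSigma)
    ch2 <- cameraNoise(ch2, spec@backgroundLevel, spec@emGain,
                       spec@readNoiseSigma)
    truth <- new("GroundTruth", molecules = molDf, marks = markDf,
                 totals = list(totalBp = sum(molDf$contourLengthBp),
                               totalLengthPx = sum(molDf$lengthPx),
                               nMarks = sum(molDf$nMarks),
                               nLabelled = sum(molDf$nLabelled)))
    new("FiberScene", channels = array(c(ch1, ch2), c(h, w, 2L)),
        truth = truth, spec = spec)
  })
}

#' Render a stepwise photobleaching trace
#'
#' Intensity of a single diffraction-limited site over time: each
#' fluorophore bleaches at an integer frame drawn from a truncated
#' exponential (all fluorophores bleach before the trace ends, at
#' distinct frames, so the trace holds exactly `nFluorophores` downward
#' steps), giving a decreasing staircase on top of the background, plus
#' additive Gaussian noise.
#'
#' @param spec a [BleachTraceSpec-class].
#' @return List with `intensity` (numeric vector of length `frames`),
#'   `stepCount` (true number of fluorophores) and `bleachFrames`
#'   (the frames after which each fluorophore is dark).
#' @examples
#' tr <- renderBleachTrace(bleachTraceSpec(nFluorophores = 2L, seed = 3L))
#' tr$stepCount
#' @export
renderBleachTrace <- function(spec) {
  stopifnot(is(spec, "BleachTraceSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    n <- spec@frames
    k <- spec@nFluorophores
    times <- integer(0)
    if (k > 0) {
      hi <- n - 1L  # last frame must sit at background
      for (attempt in 1:1000) {
        t <- ceiling(rexp(k, 1 / spec@bleachTimeMeanFrames))
        t <- t[t <= hi]
        if (length(t) == k && !anyDuplicated(t)) { times <- sort(t); break }
      }
      if (length(times) != k)  # fall back to evenly spread distinct frames
        times <- sort(sample.int(hi, k))
    }
    alive <- vapply(seq_len(n), function(f) sum(times >= f), numeric(1))
    intensity <- spec@background + spec@stepHeight * alive +
      rnorm(n, 0, spec@noiseSigma)
    list(intensity = intensity, stepCount = k, bleachFrames = times)
  })
}

#' Catalogue of tissue-level scene presets
#'
#' Named [SceneSpec-class] presets whose `markDensity` values span the
#' global 5hmC range observed across human tissues with this assay:
#' healthy colon 0.0059, adjacent colon 0.0043, healthy blood 0.0042,
#' ALL 0.0031, CRC 0.0028, MM 0.0023 and CLL 0.0019 %5hmC/dNTPs
#' (fractions of 5.9e-5 down to 1.9e-5 per base).
#'
#' @param ... overrides passed on to [sceneSpec()] (e.g. `nMolecules`,
#'   `seed`) applied to every preset.
#' @return Named list of [SceneSpec-class] objects.
#' @examples
#' names(presetScenarios())
#' presetScenarios()$healthy_colon@markDensity  # 5.9e-05
#' @export
presetScenarios <- function(...) {
  dens <- c(healthy_colon = 5.9e-5, adjacent_colon = 4.3e-5,
            healthy_blood = 4.2e-5, all = 3.1e-5, crc = 2.8e-5,
            mm = 2.3e-5, cll = 1.9e-5)
  out <- lapply(names(dens), function(nm)
    sceneSpec(markDensity = dens[[nm]], ...))
  names(out) <- names(dens)
  out
}
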