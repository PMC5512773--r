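## Backbone segmentation: background subtraction -> threshold -> cleanup
## -> thinning -> spur pruning -> path ordering and length measurement.
## Objects that remain branched (crossing molecules), touch the image
## border, are too short or too wide are discarded and logged.

#' Default backbone segmentation parameters
#'
#' @return Named list: `bgRadiusPx` (morphological-opening radius for
#'   background estimation), `smoothSigmaPx` (Gaussian pre-smoothing of
#'   the background-subtracted channel), `threshold` (`"mad"` for
#'   median + `thresholdK` x MAD robust thresholding, `"otsu"`, or a
#'   fixed count value), `thresholdK` (robust threshold multiplier),
#'   `minAreaPx` (object area floor before thinning), `minLengthPx`
#'   (minimum retained path length), `maxWidthPx` (maximum mean object
#'   width), `spurLengthPx` (skeleton spurs shorter than this are
#'   pruned). The noise-relative default is used because DNA occupies
#'   only a few percent of a field, too sparse for histogram-bisection
#'   thresholds to latch onto.
#' @examples
#' backboneParams()
#' @export
backboneParams <- function() {
  list(bgRadiusPx = 10, smoothSigmaPx = 0.7, threshold = "mad",
       thresholdK = 6, minAreaPx = 15, minLengthPx = 20, maxWidthPx = 6,
       spurLengthPx = 5)
}

## One Guo-Hall sub-iteration; returns the mask with deletable border
## pixels removed. Guo-Hall is preferred over Zhang-Suen here because it
## thins diagonal strokes to single-pixel chains without the 2-pixel
## staircase artifact (combed molecules sit at arbitrary small angles).
guoHallPass <- function(mask, phase) {
  P2 <- shiftMat(mask, 1L, 0L);  P3 <- shiftMat(mask, 1L, -1L)
  P4 <- shiftMat(mask, 0L, -1L); P5 <- shiftMat(mask, -1L, -1L)
  P6 <- shiftMat(mask, -1L, 0L); P7 <- shiftMat(mask, -1L, 1L)
  P8 <- shiftMat(mask, 0L, 1L);  P9 <- shiftMat(mask, 1L, 1L)
  C <- (!P2 & (P3 | P4)) + (!P4 & (P5 | P6)) +
    (!P6 & (P7 | P8)) + (!P8 & (P9 | P2))
  N1 <- (P9 | P2) + (P3 | P4) + (P5 | P6) + (P7 | P8)
  N2 <- (P2 | P3) + (P4 | P5) + (P6 | P7) + (P8 | P9)
  N <- pmin(N1, N2)
  m <- if (phase == 1L) (P6 | P7 | !P9) & P8 else (P2 | P3 | !P5) & P4
  mask & !(mask & C == 1L & N >= 2L & N <= 3L & !m)
}

#' Thin a binary mask to a one-pixel skeleton
#'
#' Guo–Hall iterative thinning; the result is 8-connected, preserves the
#' topology of each object, and thins strokes of any orientation to
#' single-pixel chains.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same size.
#' @examples
#' m <- matrix(FALSE, 9, 20); m[4:6, 3:18] <- TRUE
#' sum(thinMask(m))
#' @export
thinMask <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  repeat {
    m1 <- guoHallPass(mask, 1L)
    m2 <- guoHallPass(m1, 2L)
    if (identical(m2, mask)) break
    mask <- m2
  }
  mask
}

## Remove skeleton spurs: endpoint branches shorter than maxLen pixels
## that terminate at a branch point. Repeats until stable.
pruneSpurs <- function(mask, maxLen) {
  repeat {
    deg <- neighborCount8(mask)
    if (!any(mask & deg >= 3L)) break
    ends <- which(mask & deg == 1L, arr.ind = TRUE)
    removed <- FALSE
    for (e in seq_len(nrow(ends))) {
      walk <- walkFrom(mask, ends[e, ], maxSteps = maxLen,
                       stopAtBranch = TRUE)
      if (walk$hitBranch && nrow(walk$path) <= maxLen) {
        mask[walk$path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  mask
}

## Walk along a skeleton from a start pixel; returns visited pixels (as a
## 2-col matrix, excluding any branch pixel reached) and whether a branch
## point (degree >= 3) terminated the walk.
walkFrom <- function(mask, start, maxSteps = Inf, stopAtBranch = FALSE) {
  deg <- neighborCount8(mask)
  visited <- matrix(0L, 0L, 2L)
  cur <- as.integer(start)
  seen <- mask & FALSE
  repeat {
    visited <- rbind(visited, cur)
    seen[cur[1], cur[2]] <- TRUE
    if (nrow(visited) > maxSteps) break
    nb <- neighborsOf(mask, seen, cur)
    if (nrow(nb) == 0L) break
    if (stopAtBranch) {
      onBranch <- deg[cbind(nb[, 1], nb[, 2])] >= 3L
      if (any(onBranch)) return(list(path = visited, hitBranch = TRUE))
    }
    ## prefer axial moves for a clean geometric path on staircase corners
    d <- abs(nb[, 1] - cur[1]) + abs(nb[, 2] - cur[2])
    cur <- as.integer(nb[order(d, nb[, 1], nb[, 2])[1L], ])
  }
  list(path = visited, hitBranch = FALSE)
}

neighborsOf <- function(mask, seen, p) {
  rs <- p[1] + (-1:1); cs <- p[2] + (-1:1)
  keep <- rs >= 1L & rs <= nrow(mask)
  keepc <- cs >= 1L & cs <= ncol(mask)
  out <- matrix(0L, 0L, 2L)
  for (r in rs[keep]) for (c in cs[keepc]) {
    if (r == p[1] && c == p[2]) next
    if (mask[r, c] && !seen[r, c]) out <- rbind(out, c(r, c))
  }
  out
}

#' Geometric length of a traced path
#'
#' Sum of per-step Euclidean costs along an 8-connected path: 1 per
#' axial move, sqrt(2) per diagonal move. Paths shorter than two pixels
#' have no defined length and return 0 with a warning.
#'
#' @param path a [MoleculeTrace-class] or an n x 2 (row, col) matrix.
#' @return Length in pixels.
#' @examples
#' traceLengthPx(cbind(1, 1:101))          # 100
#' traceLengthPx(cbind(1:11, 1:11))        # 10 * sqrt(2)
#' @export
traceLengthPx <- function(path) {
  if (is(path, "MoleculeTrace")) path <- path@path
  stopifnot(is.matrix(path), ncol(path) == 2L)
  if (nrow(path) < 2L) {
    warning("path shorter than 2 pixels has undefined length; returning 0")
    return(0)
  }
  st <- diff(path)
  sum(sqrt(st[, 1]^2 + st[, 2]^2))
}

#' @rdname accessors
#' @export
lengthPx <- function(x) {
  stopifnot(is(x, "MoleculeTrace"))
  x@lengthPx
}

#' Segment and trace DNA backbones
#'
#' Runs the full backbone pipeline on the intercalator channel:
#' morphological-opening background subtraction, light Gaussian
#' smoothing, robust noise-relative (or Otsu, or fixed) thresholding,
#' removal of sub-area debris, Guo–Hall thinning, spur
#' pruning, then discarding of objects that still contain branch points
#' (crossing/overlapping molecules), touch the image border, are wider
#' than `maxWidthPx` on average, or are shorter than `minLengthPx`.
#' Retained skeletons are ordered endpoint-to-endpoint. Deterministic
#' for a fixed input.
#'
#' @param img 2-D numeric matrix (backbone channel).
#' @param params parameter list as from [backboneParams()]; missing
#'   entries take defaults.
#' @return List with `molecules` (list of [MoleculeTrace-class]) and
#'   `discards` (data.frame `label`, `reason` with reasons `"branched"`,
#'   `"border"`, `"wide"`, `"short"`, `"small"`).
#' @examples
#' sc <- renderScene(sceneSpec(imageHeightPx = 256L, imageWidthPx = 256L,
#'                             nMolecules = 3L, seed = 2L))
#' bb <- segmentBackbones(sceneChannels(sc)[, , 1])
#' length(bb$molecules)
#' @export
segmentBackbones <- function(img, params = backboneParams()) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("backbone channel must be a 2-D numeric matrix")
  params <- modifyList(backboneParams(), params)
  emptyLog <- data.frame(label = integer(), reason = character())
  empty <- list(molecules = list(), discards = emptyLog)
  if (all(img == img[1])) return(empty)   # flat image: nothing to segment

  storage.mode(img) <- "double"
  brush <- EBImage::makeBrush(2L * as.integer(params$bgRadiusPx) + 1L, "disc")
  bg <- EBImage::opening(img, brush)
  sub <- pmax(img - bg, 0)
  if (params$smoothSigmaPx > 0)
    sub <- gaussBlur(sub, params$smoothSigmaPx)
  mx <- max(sub)
  if (mx <= 0) return(empty)
  thr <- if (identical(params$threshold, "mad")) {
    median(sub) + params$thresholdK * max(mad(sub), .Machine$double.eps)
  } else if (identical(params$threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(sub / mx), range = c(0, 1)) * mx
  } else {
    checkRange(params$threshold, "threshold", lo = 0, lo.open = TRUE)
  }
  mask <- sub > thr
  lab <- EBImage::imageData(EBImage::bwlabel(mask + 0L))
  nObj <- max(lab)
  if (nObj == 0L) return(empty)

  h <- nrow(img); w <- ncol(img)
  molecules <- list()
  nextId <- 1L
  idx <- split(which(lab > 0), lab[lab > 0])
  reasons <- character(nObj)
  for (o in seq_len(nObj)) {
    pix <- idx[[as.character(o)]]
    area <- length(pix)
    if (area < params$minAreaPx) { reasons[o] <- "small"; next }
    rr <- (pix - 1L) %% h + 1L
    cc <- (pix - 1L) %/% h + 1L
    if (any(rr == 1L | rr == h | cc == 1L | cc == w)) {
      reasons[o] <- "border"; next
    }
    r0 <- min(rr) - 1L; c0 <- min(cc) - 1L
    sub.h <- max(rr) - r0 + 2L; sub.w <- max(cc) - c0 + 2L
    m <- matrix(FALSE, sub.h, sub.w)
    m[cbind(rr - r0, cc - c0)] <- TRUE
    sk <- pruneSpurs(thinMask(m), params$spurLengthPx)
    deg <- neighborCount8(sk)
    if (any(sk & deg >= 3L)) { reasons[o] <- "branched"; next }
    endpoints <- which(sk & deg == 1L, arr.ind = TRUE)
    if (nrow(endpoints) != 2L) {  # loop or fragmented skeleton
      reasons[o] <- "branched"; next
    }
    ord <- order(endpoints[, 1], endpoints[, 2])
    walk <- walkFrom(sk, endpoints[ord[1L], ])
    if (nrow(walk$path) != sum(sk)) { reasons[o] <- "branched"; next }
    len <- traceLengthPx(walk$path)
    if (len < params$minLengthPx) { reasons[o] <- "short"; next }
    if (area / max(len, 1) > params$maxWidthPx) { reasons[o] <- "wide"; next }
    path <- cbind(walk$path[, 1] + r0, walk$path[, 2] + c0)
    colnames(path) <- c("row", "col")
    molecules[[nextId]] <- new("MoleculeTrace", id = nextId,
                               path = path, lengthPx = len,
                               meanIntensity = mean(img[path]),
                               flags = character(0))
    nextId <- nextId + 1L
  }
  disc <- which(reasons != "")
  list(molecules = molecules,
       discards = data.frame(label = disc, reason = reasons[disc]))
}
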