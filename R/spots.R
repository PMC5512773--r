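## Diffraction-limited spot detection in the 5hmC label channel:
## difference-of-Gaussians band-pass at the PSF scale, local maxima,
## noise-relative (MAD) thresholding and weighted-centroid subpixel
## refinement.

#' Default spot detection parameters
#'
#' @return Named list: `psfSigmaPx` (expected PSF sigma in pixels;
#'   0.8125 px = 130 nm at 160 nm/px), `thresholdK` (threshold in robust
#'   noise units, k x MAD of the filter response), `minSeparationPx`
#'   (maxima closer than this are merged, keeping the brighter),
#'   `centroidRadiusPx` (half-width of the centroid window).
#' @examples
#' spotParams()
#' @export
spotParams <- function() {
  list(psfSigmaPx = 130 / 160, thresholdK = 6, minSeparationPx = 2,
       centroidRadiusPx = 2)
}

## 3x3 greatest-neighbour image (excluding the centre pixel)
maxNeighbor <- function(m) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, shiftMat(m, dr, dc))
  }
  out
}

#' Detect fluorescent spots with subpixel localization
#'
#' Band-pass filters the image with a difference of Gaussians at the PSF
#' scale (`sigma` and `1.6 sigma`), finds local maxima of the response,
#' keeps those exceeding `thresholdK` times the robust noise level
#' (1.4826 x median absolute deviation of the response), merges maxima
#' closer than `minSeparationPx` keeping the brighter, and refines each
#' peak to a subpixel centroid weighted by the background-subtracted
#' intensity in a `(2r+1)^2` window. The threshold is noise-relative, so
#' detections are invariant to rescaling the image by a positive
#' constant.
#'
#' @param img 2-D numeric matrix (label channel).
#' @param params parameter list as from [spotParams()]; missing entries
#'   take defaults.
#' @return data.frame with one row per spot: `row`, `col` (subpixel
#'   centroid), `peak` (peak intensity above local background),
#'   `integrated` (summed background-subtracted intensity in the
#'   centroid window) and `score` (filter response in noise units).
#'   Sorted by decreasing score.
#' @examples
#' img <- renderEmitters(c(16.3, 20.7), c(32, 40), 0.8, 100)
#' detectSpots(img + 1)[, c("row", "col")]
#' @export
detectSpots <- function(img, params = spotParams()) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("label channel must be a 2-D numeric matrix")
  params <- modifyList(spotParams(), params)
  checkRange(params$psfSigmaPx, "psfSigmaPx", lo = 0, lo.open = TRUE)
  checkRange(params$thresholdK, "thresholdK", lo = 0, lo.open = TRUE)
  checkRange(params$minSeparationPx, "minSeparationPx", lo = 0)

  storage.mode(img) <- "double"
  out0 <- data.frame(row = numeric(), col = numeric(), peak = numeric(),
                     integrated = numeric(), score = numeric())
  if (diff(range(img)) == 0) return(out0)  # flat field: nothing to detect
  s1 <- params$psfSigmaPx
  resp <- gaussBlur(img, s1) - gaussBlur(img, 1.6 * s1)
  noise <- mad(resp)
  if (noise <= 0) noise <- max(sd(resp), .Machine$double.eps)
  cand <- which(resp >= maxNeighbor(resp) & resp > params$thresholdK * noise)
  out <- data.frame(row = numeric(), col = numeric(), peak = numeric(),
                    integrated = numeric(), score = numeric())
  if (!length(cand)) return(out)
  h <- nrow(img); w <- ncol(img)
  cr <- (cand - 1L) %% h + 1L
  cc <- (cand - 1L) %/% h + 1L
  o <- order(-resp[cand], cr, cc)
  cr <- cr[o]; cc <- cc[o]; cv <- resp[cand][o]

  ## greedy merge: strongest first, suppress weaker maxima within minSep
  keep <- logical(length(cr))
  for (i in seq_along(cr)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cr[keep] - cr[i])^2 + (cc[keep] - cc[i])^2
    if (all(d2 >= params$minSeparationPx^2)) keep[i] <- TRUE
  }
  cr <- cr[keep]; cc <- cc[keep]; cv <- cv[keep]

  r <- as.integer(params$centroidRadiusPx)
  res <- lapply(seq_along(cr), function(i) {
    rs <- max(1L, cr[i] - r):min(h, cr[i] + r)
    cs <- max(1L, cc[i] - r):min(w, cc[i] + r)
    win <- img[rs, cs, drop = FALSE]
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    bg <- median(border)
    wgt <- pmax(win - bg, 0)
    tot <- sum(wgt)
    if (tot <= 0) {
      ctr <- c(cr[i], cc[i])
    } else {
      ctr <- c(sum(wgt * rs) / tot,
               sum(t(wgt) * cs) / tot)
    }
    c(ctr[1], ctr[2], img[cr[i], cc[i]] - bg, tot, cv[i] / noise)
  })
  res <- do.call(rbind, res)
  data.frame(row = res[, 1], col = res[, 2], peak = res[, 3],
             integrated = res[, 4], score = res[, 5])
}
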