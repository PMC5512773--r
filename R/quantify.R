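## Sample-level quantification: raw spot density, convergence and
## split-half reproducibility statistics, calibration to absolute
## %5hmC/dNTPs, and group comparison.

#' Raw 5hmC spot density
#'
#' Total collocalized spots divided by total traced DNA length in
#' pixels. Pooled image sets must be combined by summing numerators and
#' denominators (the density of the concatenated totals), never by
#' averaging per-set densities.
#'
#' @param totalSpots total number of collocalized spots.
#' @param totalLengthPx total DNA length in pixels (> 0).
#' @return Spots per pixel.
#' @examples
#' rawDensity(10, 1e4)  # 1e-3
#' @export
rawDensity <- function(totalSpots, totalLengthPx) {
  stopifnot(is.numeric(totalSpots), is.numeric(totalLengthPx))
  if (totalLengthPx <= 0)
    stop("undefined density: total DNA length must be > 0")
  totalSpots / totalLengthPx
}

#' Running-density convergence curve
#'
#' Accumulates molecules in acquisition order and plots the running
#' density (cumulative spots / cumulative length) against cumulative DNA
#' length. The sample is flagged converged when, over the trailing
#' `tailFraction` of cumulative length, the running density never
#' deviates from the final density by more than `tolerance` (relative).
#' A single molecule is never converged. The endpoint (final density)
#' is order-invariant; only the shape of the curve depends on order.
#'
#' @param lengthsPx per-molecule DNA lengths in acquisition order.
#' @param nSpots per-molecule collocalized spot counts, same order.
#' @param tolerance relative plateau tolerance (default 0.05).
#' @param tailFraction trailing fraction of cumulative length examined
#'   (default 0.2).
#' @return A [ConvergenceCurve-class].
#' @examples
#' cc <- convergenceCurve(rep(100, 50), rpois(50, 2))
#' cc@converged
#' @export
convergenceCurve <- function(lengthsPx, nSpots, tolerance = 0.05,
                             tailFraction = 0.2) {
  stopifnot(length(lengthsPx) == length(nSpots), length(lengthsPx) >= 1L,
            all(lengthsPx > 0))
  checkRange(tolerance, "tolerance", lo = 0, lo.open = TRUE)
  checkRange(tailFraction, "tailFraction", lo = 0, hi = 1, lo.open = TRUE)
  cl <- cumsum(lengthsPx)
  cs <- cumsum(nSpots)
  dens <- cs / cl
  pts <- data.frame(cumLengthPx = cl, cumSpots = cs, density = dens)
  n <- length(cl)
  final <- dens[n]
  if (n == 1L) {
    conv <- FALSE
  } else {
    tail.idx <- which(cl >= (1 - tailFraction) * cl[n])
    if (length(tail.idx) < 2L) tail.idx <- c(n - 1L, n)
    conv <- if (final == 0) {
      all(dens[tail.idx] == 0)
    } else {
      max(abs(dens[tail.idx] - final)) / final <= tolerance
    }
  }
  new("ConvergenceCurve", points = pts,
      moleculeOrder = seq_len(n), converged = conv,
      tolerance = tolerance, tailFraction = tailFraction)
}

#' Split-half reproducibility statistic
#'
#' Randomly divides the molecules of a sample into two groups containing
#' similar total DNA and compares their densities: molecules are
#' shuffled with `seed`, then assigned longest-first to whichever group
#' has the smaller running length, so group totals typically agree
#' within a few percent. Returns the two-value sample standard deviation
#' of the group densities divided by their mean, as a percentage
#' (`|d1 - d2| / sqrt(2) / mean * 100`). Samples with enough DNA for a
#' converged estimate show values well under 10%.
#'
#' @param lengthsPx per-molecule DNA lengths (>= 2 molecules).
#' @param nSpots per-molecule collocalized spot counts.
#' @param seed shuffle seed.
#' @param balanceTol relative group-length imbalance above which the
#'   `balanced` flag is set FALSE (with a warning); default 0.05.
#' @return List: `relativeSD` (%), `groupDensities`, `groupLengthsPx`,
#'   `groupSpots`, `balanced`.
#' @examples
#' splitHalfSD(rep(100, 40), rpois(40, 3), seed = 1L)$relativeSD
#' @export
splitHalfSD <- function(lengthsPx, nSpots, seed = 1L, balanceTol = 0.05) {
  stopifnot(length(lengthsPx) == length(nSpots))
  if (length(lengthsPx) < 2L)
    stop("split-half statistic needs at least 2 molecules")
  withSeed(seed, {
    perm <- sample.int(length(lengthsPx))
    perm <- perm[order(-lengthsPx[perm])]  # longest first; shuffle breaks ties
    grp <- integer(length(perm))
    tot <- c(0, 0)
    for (i in perm) {
      g <- if (tot[1] <= tot[2]) 1L else 2L
      grp[i] <- g
      tot[g] <- tot[g] + lengthsPx[i]
    }
    sp <- c(sum(nSpots[grp == 1L]), sum(nSpots[grp == 2L]))
    d <- sp / tot
    imbalance <- abs(tot[1] - tot[2]) / mean(tot)
    balanced <- imbalance < balanceTol
    if (!balanced)
      warning(sprintf(
        "could not balance group DNA within %.0f%% (imbalance %.1f%%)",
        100 * balanceTol, 100 * imbalance))
    rel <- if (mean(d) == 0) 0 else abs(d[1] - d[2]) / sqrt(2) / mean(d) * 100
    list(relativeSD = rel, groupDensities = d, groupLengthsPx = tot,
         groupSpots = sp, balanced = balanced)
  })
}

#' Calibrate raw density to absolute %5hmC/dNTPs
#'
#' Converts a raw spot density `D` (spots per pixel of traced DNA) into
#' the percentage of 5hmC bases among all nucleotides:
#' `%5hmC = 100 * (D * C / eps) / bpPerPx`, where `C` is the
#' photobleaching-derived cluster correction, `eps` the labelling
#' efficiency and `bpPerPx = pixelSizeNm / (0.34 * stretchFactor)` the
#' bases of DNA represented by one pixel. If the model carries a
#' side-by-side reference standard, the result is further rescaled by
#' `referenceKnownPercent / (calibrated percent of the reference)`,
#' normalizing between experiments. The output is linear in `D`.
#'
#' @param density raw density in spots per pixel.
#' @param model a [CalibrationModel-class].
#' @return %5hmC/dNTPs (e.g. 0.0059 means 0.0059%).
#' @examples
#' m <- calibrationModel(labellingEfficiency = 0.8, stretchFactor = 0.85,
#'                       pixelSizeNm = 160, clusterCorrection = 1.2)
#' percent5hmC(1e-3, m)  # about 2.71e-4
#' @export
percent5hmC <- function(density, model) {
  stopifnot(is(model, "CalibrationModel"))
  validObject(model)
  stopifnot(is.numeric(density), all(density >= 0))
  base <- 100 * (density * model@clusterCorrection /
                   model@labellingEfficiency) / bpPerPx(model)
  if (!is.na(model@referenceKnownPercent)) {
    ref <- 100 * (model@referenceMeasuredDensity * model@clusterCorrection /
                    model@labellingEfficiency) / bpPerPx(model)
    base <- base * model@referenceKnownPercent / ref
  }
  base
}

#' Compare %5hmC between two sample groups
#'
#' Reports group means, the fold change (mean A / mean B) and a
#' two-sided two-sample location test: Welch's t-test by default, or
#' Mann-Whitney (`test = "wilcoxon"`).
#'
#' @param groupA,groupB numeric vectors of per-sample %5hmC (each
#'   length >= 2).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return List: `meanA`, `meanB`, `foldChange`, `pValue`, `test`,
#'   `nA`, `nB`.
#' @examples
#' compareGroups(c(0.0059, 0.0055, 0.0062), c(0.0028, 0.0031, 0.0026))
#' @export
compareGroups <- function(groupA, groupB, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 samples")
  ht <- if (test == "welch") {
    t.test(groupA, groupB, var.equal = FALSE)
  } else {
    wilcox.test(groupA, groupB, exact = FALSE)
  }
  list(meanA = mean(groupA), meanB = mean(groupB),
       foldChange = mean(groupA) / mean(groupB),
       pValue = ht$p.value, test = test,
       nA = length(groupA), nB = length(groupB))
}
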