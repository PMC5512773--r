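## Photobleaching step counting: exact dynamic-programming change-point
## fit of piecewise-constant traces with a BIC-style penalty, and the
## fluorophores-per-site distribution that feeds the cluster correction.

## residual sum of squares of trace segments [i, j] for all i <= j,
## via cumulative sums; returns a function cost(i, j) vectorized over i
segmentCostFun <- function(x) {
  c1 <- c(0, cumsum(x)); c2 <- c(0, cumsum(x^2))
  function(i, j) {
    n <- j - i + 1
    s <- c1[j + 1] - c1[i]
    pmax(c2[j + 1] - c2[i] - s^2 / n, 0)
  }
}

#' Fit a piecewise-constant model to a photobleaching trace
#'
#' Exact dynamic programming over all change-point positions, minimizing
#' `RSS + penalty * m * log(n)` where `m` is the number of change points.
#' Segment levels are segment means; the step count is the number of
#' change points at which the level decreases (upward jumps — blinking —
#' are fitted but not counted). Ties are resolved towards fewer change
#' points, so the fit is deterministic.
#'
#' The default penalty is `3 * sigma^2`, with `sigma` estimated robustly
#' from the first differences of the trace (`mad(diff(x)) / sqrt(2)`);
#' because the penalty scales with the noise variance, the fitted step
#' count is invariant to affine transforms of the intensity scale.
#'
#' @param trace numeric intensity series (length >= 3).
#' @param penalty per-change-point cost multiplying `log(n)`; `NULL`
#'   (default) uses the noise-scaled automatic penalty.
#' @return A [StepFit-class].
#' @examples
#' fitSteps(c(200, 200, 100, 100, 0, 0))  # two downward steps
#' @export
fitSteps <- function(trace, penalty = NULL) {
  if (length(trace) == 0L) stop("empty trace")
  if (!is.numeric(trace) || length(trace) < 3L)
    stop("trace must be a numeric series of length >= 3")
  x <- as.numeric(trace)
  n <- length(x)
  if (is.null(penalty)) {
    sig <- mad(diff(x)) / sqrt(2)
    penalty <- 3 * sig^2
  }
  if (penalty < 0) stop("penalty must be >= 0")
  beta <- max(penalty, 1e-12 * max(1, mean(x^2))) * log(n)
  cost <- segmentCostFun(x)

  ## F[j+1]: optimal cost of x[1..j]; K: change points used; bp: argmin
  F <- c(-beta, rep(Inf, n))
  K <- integer(n + 1L)
  bp <- integer(n + 1L)
  for (j in seq_len(n)) {
    i <- seq_len(j)
    cand <- F[i] + cost(i, j) + beta
    best <- min(cand)
    ok <- which(cand <= best + 1e-9)
    pick <- ok[order(K[ok], ok)[1L]]  # fewest change points, then earliest
    F[j + 1L] <- cand[pick]
    K[j + 1L] <- K[pick] + 1L
    bp[j + 1L] <- pick
  }
  ## backtrack segment boundaries
  ends <- integer(0)
  j <- n
  while (j > 0L) {
    i <- bp[j + 1L]
    ends <- c(i - 1L, ends)
    j <- i - 1L
  }
  cps <- ends[ends > 0L]
  cps <- cps[cps < n]
  starts <- c(1L, cps + 1L)
  stops <- c(cps, n)
  levels <- vapply(seq_along(starts),
                   function(k) mean(x[starts[k]:stops[k]]), numeric(1))
  stepCount <- if (length(levels) > 1L) sum(diff(levels) < 0) else 0L
  new("StepFit", changePoints = as.integer(cps), levels = levels,
      stepCount = as.integer(stepCount), score = F[n + 1L])
}

#' Distribution of fluorophores per resolvable site
#'
#' Tabulates downward step counts across fitted traces into the
#' probability `p[k]` that a diffraction-limited 5hmC site carries `k`
#' fluorophores. Traces with zero steps carry no fluorophore, hence no
#' site, and are excluded. Counts above `Kmax` are truncated into the
#' `Kmax` bin.
#'
#' @param fits list of [StepFit-class] objects (or an integer vector of
#'   step counts).
#' @param Kmax largest cluster size tracked.
#' @return A [ClusterDist-class].
#' @examples
#' clusterDistribution(c(1L, 1L, 1L, 1L, 2L))  # p1 = 0.8, p2 = 0.2
#' @export
clusterDistribution <- function(fits, Kmax = 5L) {
  counts <- if (is.list(fits)) {
    vapply(fits, stepCount, integer(1))
  } else {
    as.integer(fits)
  }
  counts <- counts[counts >= 1L]
  if (!length(counts))
    stop("no analyzable sites: all traces have zero bleaching steps")
  counts <- pmin(counts, as.integer(Kmax))
  p <- tabulate(counts, nbins = as.integer(Kmax)) / length(counts)
  names(p) <- seq_len(Kmax)
  new("ClusterDist", p = p, nTraces = length(counts))
}

#' Cluster-correction factor
#'
#' Mean number of fluorophores per resolvable 5hmC site,
#' `C = sum(k * p[k])`. Because nearby 5hmC residues within the
#' diffraction limit merge into one spot, the raw spot density
#' undercounts marks by this factor; multiplying by `C` during
#' calibration corrects it. `C >= 1`, with equality exactly when every
#' site holds a single fluorophore.
#'
#' @param dist a [ClusterDist-class].
#' @return The correction factor `C`.
#' @examples
#' clusterCorrection(clusterDistribution(c(1L, 1L, 1L, 1L, 2L)))  # 1.2
#' @export
clusterCorrection <- function(dist) {
  stopifnot(is(dist, "ClusterDist"))
  sum(seq_along(dist@p) * dist@p)
}
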