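# Independent oracles and shared fixtures for the test suite.

# Brute-force change-point oracle: enumerate change-point subsets and
# minimize RSS + beta * |S| directly. Enumerates every subset for short
# traces, otherwise all subsets up to `maxCp` change points. Independent
# of the dynamic program it checks.
bruteForceStepCost <- function(x, penalty = NULL, maxCp = 3L) {
  n <- length(x)
  if (is.null(penalty)) {
    sig <- mad(diff(x)) / sqrt(2)
    penalty <- 3 * sig^2
  }
  beta <- max(penalty, 1e-12 * max(1, mean(x^2))) * log(n)
  rssOf <- function(cps) {
    bounds <- c(0L, cps, n)
    s <- 0
    for (k in seq_len(length(bounds) - 1L)) {
      seg <- x[(bounds[k] + 1L):bounds[k + 1L]]
      s <- s + sum((seg - mean(seg))^2)
    }
    s
  }
  best <- list(cost = rssOf(integer(0)), cps = integer(0))
  positions <- seq_len(n - 1L)
  subsets <- if (n <= 14L) {
    unlist(lapply(seq_len(n - 1L), function(m)
      utils::combn(positions, m, simplify = FALSE)), recursive = FALSE)
  } else {
    unlist(lapply(seq_len(maxCp), function(m)
      utils::combn(positions, m, simplify = FALSE)), recursive = FALSE)
  }
  for (cps in subsets) {
    cost <- rssOf(cps) + beta * length(cps)
    if (cost < best$cost - 1e-12) best <- list(cost = cost, cps = cps)
  }
  best$cost <- best$cost
  best
}

# Downward steps of an explicit segmentation (oracle-side step counter).
stepsOfSegmentation <- function(x, cps) {
  bounds <- c(0L, cps, length(x))
  lev <- vapply(seq_len(length(bounds) - 1L), function(k)
    mean(x[(bounds[k] + 1L):bounds[k + 1L]]), numeric(1))
  if (length(lev) > 1L) sum(diff(lev) < 0) else 0L
}

# Match detected spots against true emitter positions within `tol` px;
# greedy one-to-one matching by distance.
spotMatchStats <- function(truth, det, tol = 2) {
  if (!is.matrix(truth)) truth <- matrix(truth, ncol = 2)
  nT <- nrow(truth); nD <- nrow(det)
  if (nT == 0L || nD == 0L)
    return(list(tp = 0L, fn = nT, fp = nD))
  d <- sqrt(outer(truth[, 1], det$row, "-")^2 +
              outer(truth[, 2], det$col, "-")^2)
  tp <- 0L
  repeat {
    m <- which.min(d)
    if (d[m] > tol) break
    i <- (m - 1L) %% nT + 1L; j <- (m - 1L) %/% nT + 1L
    tp <- tp + 1L
    d[i, ] <- Inf; d[, j] <- Inf
    if (!is.finite(min(d))) break
  }
  list(tp = tp, fn = nT - tp, fp = nD - tp)
}

# Shared simulation cache so acceptance blocks that need the same
# full-scale sample do not recompute it.
.simCache <- new.env(parent = emptyenv())

# Full-scale sample at acceptance conditions: 14 fields of 90 molecules
# (about 1,260 molecules placed, > 1,000 retained), ideal labelling.
accSample <- function(density, seedBase, nScenes = 14L) {
  seedBase <- as.integer(seedBase)
  key <- sprintf("d%g_s%d_n%d", density, seedBase, nScenes)
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  spec <- sceneSpec(markDensity = density, seed = as.integer(seedBase))
  cfg <- runConfig(seed = as.integer(seedBase))
  sim <- simulateSample(spec, nScenes = nScenes, config = cfg)
  .simCache[[key]] <- sim
  sim
}

presetDensities <- c(healthy_colon = 5.9e-5, healthy_blood = 4.2e-5,
                     all = 3.1e-5, crc = 2.8e-5, mm = 2.3e-5,
                     cll = 1.9e-5)
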