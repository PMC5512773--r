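## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so simulation calls are reproducible without
#' clobbering the session stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    has.old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has.old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has.old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Shift a matrix by (dr, dc) with zero fill
#'
#' `out[r, c] == m[r - dr, c - dc]` where defined, else 0/FALSE.
#' @noRd
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(vector(typeof(m), 1L), nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## number of TRUE 8-neighbours per pixel of a logical matrix
neighborCount8 <- function(mask) {
  s <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    s <- s + shiftMat(mask, dr, dc)
  }
  s
}

## Separable Gaussian blur with replicate edge padding. Spatial-domain
## convolution (two 1-D passes) — much faster than FFT filtering for the
## small kernels used at PSF scale.
gaussBlur <- function(m, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pr <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  pc <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  mp <- m[pr, pc]
  y <- stats::filter(mp, k, sides = 2)     # filters each column
  y <- t(stats::filter(t(y), k, sides = 2))
  out <- y[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
  matrix(as.numeric(out), nrow(m), ncol(m))
}

## stop() with the offending field named; used by config/spec validation
failField <- function(field, why) {
  stop(sprintf("invalid value for '%s': %s", field, why), call. = FALSE)
}

checkRange <- function(value, field, lo = -Inf, hi = Inf,
                       lo.open = FALSE, hi.open = FALSE, len = 1L) {
  if (!is.numeric(value) || length(value) != len || anyNA(value))
    failField(field, sprintf("must be numeric of length %d", len))
  bad <- if (lo.open) any(value <= lo) else any(value < lo)
  bad <- bad || if (hi.open) any(value >= hi) else any(value > hi)
  if (bad)
    failField(field, sprintf("must lie in %s%g, %g%s",
                             if (lo.open) "(" else "[", lo, hi,
                             if (hi.open) ")" else "]"))
  invisible(value)
}
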