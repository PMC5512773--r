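## Colocalization: assign each detected spot to the nearest traced
## molecule within a distance tolerance; the rest are orphans.

#' Assign spots to traced molecules
#'
#' Each spot (after applying the optional constant channel offset) is
#' measured against every molecule's path pixels; it is assigned to the
#' molecule with the smallest minimum Euclidean distance provided that
#' distance is at most `maxDistPx`, otherwise it is an orphan. Ties in
#' distance are broken towards the lower molecule id, so assignment is
#' deterministic. Every spot goes to at most one molecule and assigned
#' plus orphan counts always sum to the number of detections.
#'
#' @param molecules list of [MoleculeTrace-class] objects.
#' @param spots spot table from [detectSpots()].
#' @param maxDistPx maximum spot-to-path distance in pixels (> 0);
#'   default 2 px (about 320 nm at 160 nm/px) covers localization error
#'   plus label linker length.
#' @param offsetPx constant label-channel registration offset
#'   `c(dRow, dCol)` added to spot coordinates before assignment.
#' @return List with `molecules` (list of [LabeledMolecule-class]),
#'   `orphans` (data.frame of unassigned spots) and `assignments`
#'   (data.frame `spot`, `molecule` — NA for orphans — and `distancePx`).
#' @examples
#' tr <- new("MoleculeTrace", id = 1L, path = cbind(5L, 2:9),
#'           lengthPx = 7, meanIntensity = 1, flags = character(0))
#' sp <- data.frame(row = 5, col = 4, peak = 1, integrated = 1, score = 9)
#' assignSpots(list(tr), sp)$assignments
#' @export
assignSpots <- function(molecules, spots, maxDistPx = 2,
                        offsetPx = c(0, 0)) {
  checkRange(maxDistPx, "maxDistPx", lo = 0, lo.open = TRUE)
  stopifnot(is.data.frame(spots),
            all(c("row", "col") %in% names(spots)))
  ids <- vapply(molecules, function(m) m@id, integer(1))
  nSpot <- nrow(spots)
  assign.df <- data.frame(spot = seq_len(nSpot),
                          molecule = rep(NA_integer_, nSpot),
                          distancePx = rep(NA_real_, nSpot))
  if (nSpot && length(molecules)) {
    sr <- spots$row + offsetPx[1]
    sc <- spots$col + offsetPx[2]
    ## distance of every spot to every molecule's nearest path pixel
    dmin <- matrix(Inf, nSpot, length(molecules))
    for (j in seq_along(molecules)) {
      p <- molecules[[j]]@path
      for (i in seq_len(nSpot))
        dmin[i, j] <- sqrt(min((p[, 1] - sr[i])^2 + (p[, 2] - sc[i])^2))
    }
    for (i in seq_len(nSpot)) {
      best <- min(dmin[i, ])
      if (best <= maxDistPx) {
        cand <- which(dmin[i, ] <= best + 1e-9)
        j <- cand[which.min(ids[cand])]
        assign.df$molecule[i] <- ids[j]
        assign.df$distancePx[i] <- dmin[i, j]
      } else {
        assign.df$distancePx[i] <- best
      }
    }
  } else if (nSpot) {
    assign.df$distancePx <- Inf
  }
  labeled <- lapply(molecules, function(m) {
    sel <- which(assign.df$molecule == m@id)
    sp <- spots[sel, , drop = FALSE]
    sp$distancePx <- assign.df$distancePx[sel]
    new("LabeledMolecule", trace = m, spots = sp,
        nSpots = length(sel))
  })
  orphan.idx <- which(is.na(assign.df$molecule))
  list(molecules = labeled,
       orphans = spots[orphan.idx, , drop = FALSE],
       assignments = assign.df)
}

#' @rdname accessors
#' @export
spotCount <- function(x) { stopifnot(is(x, "LabeledMolecule")); x@nSpots }
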