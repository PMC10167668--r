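# Peak detection in circular Ringer traces.
#
# A peak is a local maximum of the circularized trace at or above the sigma
# threshold with sufficient circular prominence; maxima closer than the
# minimum separation are merged keeping the higher.  The peak area
# integrates the raw sigma values (baseline zero, not value-minus-threshold)
# over the contiguous super-threshold run containing the maximum, by the
# trapezoid rule in degrees; runs shared by several accepted peaks are split
# at the lowest sample between them.

#' Find density peaks in a circular Ringer trace
#'
#' @param trace A \code{RingerTrace}.
#' @param threshold Detection threshold in sigma units (default 0.3, the
#'   conventional floor for detecting weakly populated conformations; the
#'   published evaluation preset of 0.35 is available via
#'   \code{paperEvalThreshold()}).
#' @param minProminence Minimum circular prominence in sigma units
#'   (default 0.1; suppresses shoulder double-counting at 10 degree
#'   sampling).
#' @param minSeparation Minimum angular separation between peaks in degrees
#'   (default 30); closer maxima are merged keeping the higher.
#' @return data.frame with one row per peak, sorted by descending height:
#'   chain, resno, insert, restype, chi, angle (deg in [0, 360)), height
#'   (sigma), area (sigma x degrees).
#' @export
findDensityPeaks <- function(trace, threshold = 0.3, minProminence = 0.1,
                             minSeparation = 30) {
  stopifnot(threshold >= 0)
  v <- trace@values
  m <- length(v)
  step <- trace@step
  empty <- data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), restype = character(0),
                      chi = integer(0), angle = numeric(0),
                      height = numeric(0), area = numeric(0))
  nxt <- function(i) (i %% m) + 1L
  prv <- function(i) ((i - 2L) %% m) + 1L
  # local maxima of the circularized trace (strict on the left, ties kept
  # once on the right so a 2-sample plateau yields a single maximum)
  cand <- which(vapply(seq_len(m), function(i)
    v[i] > v[prv(i)] && v[i] >= v[nxt(i)], logical(1)))
  cand <- cand[v[cand] >= threshold]
  if (length(cand) == 0L) return(empty)

  prominence <- function(i) {
    walk <- function(stepper) {
      j <- stepper(i)
      lo <- v[i]
      while (j != i) {
        if (v[j] > v[i]) return(c(found = 1, lo = lo))
        lo <- min(lo, v[j])
        j <- stepper(j)
      }
      c(found = 0, lo = lo)
    }
    L <- walk(prv)
    R <- walk(nxt)
    key <- if (L["found"] == 1 && R["found"] == 1) max(L["lo"], R["lo"])
           else if (L["found"] == 1) L["lo"]
           else if (R["found"] == 1) R["lo"]
           else min(v)
    v[i] - key
  }
  cand <- cand[vapply(cand, prominence, numeric(1)) >= minProminence]
  if (length(cand) == 0L) return(empty)

  # merge: accept by descending height, reject anything within minSeparation
  ang <- trace@angles[cand]
  ord <- order(-v[cand], ang)
  accepted <- integer(0)
  for (i in cand[ord]) {
    if (length(accepted) == 0L ||
        all(circularDiff(trace@angles[i], trace@angles[accepted]) >=
            minSeparation))
      accepted <- c(accepted, i)
  }

  # contiguous circular super-threshold runs
  above <- v >= threshold
  runId <- integer(m)
  rid <- 0L
  for (i in seq_len(m)) {
    if (!above[i]) next
    if (above[prv(i)] && runId[prv(i)] > 0L && i != 1L)
      runId[i] <- runId[prv(i)]
    else {
      rid <- rid + 1L
      runId[i] <- rid
    }
  }
  # circular closure: merge the run wrapping through index 1
  if (above[1L] && above[m] && runId[1L] != runId[m])
    runId[runId == runId[m]] <- runId[1L]

  trapezoid <- function(idx) {
    # idx: ordered indices of a contiguous (circularly) run segment
    if (length(idx) == 1L) return(v[idx] * step)
    sum((v[idx[-length(idx)]] + v[idx[-1L]]) / 2 * step)
  }
  runIndices <- function(r) {
    idx <- which(runId == r)
    if (length(idx) == m) {
      # everything super-threshold: cut the circle at its global minimum
      start <- which.min(v)
      idx <- c(idx[start:m], idx[seq_len(start - 1L)])
    } else if (any(diff(idx) > 1L)) {
      # wrapped run: rotate so the segment is contiguous
      brk <- which(diff(idx) > 1L)
      idx <- c(idx[(brk + 1L):length(idx)], idx[seq_len(brk)])
    }
    idx
  }
  area <- numeric(length(accepted))
  for (r in unique(runId[accepted])) {
    idx <- runIndices(r)
    inRun <- accepted[runId[accepted] == r]
    if (length(inRun) == 1L) {
      area[match(inRun, accepted)] <- trapezoid(idx)
    } else {
      # split the run at the lowest sample between consecutive peaks
      pos <- match(inRun, idx)
      o <- order(pos)
      cuts <- integer(0)
      for (k in seq_len(length(o) - 1L)) {
        seg <- (pos[o[k]]):(pos[o[k + 1L]])
        cuts <- c(cuts, seg[which.min(v[idx[seg]])])
      }
      bounds <- c(1L, cuts, length(idx))
      for (k in seq_along(o)) {
        seg <- idx[bounds[k]:bounds[k + 1L]]
        area[match(inRun[o[k]], accepted)] <- trapezoid(seg)
      }
    }
  }
  out <- data.frame(chain = trace@chain, resno = trace@resno,
                    insert = trace@insert, restype = trace@restype,
                    chi = trace@chiIndex, angle = trace@angles[accepted],
                    height = v[accepted], area = area)
  out <- out[order(-out$height, out$angle), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The published evaluation threshold
#'
#' The benchmark evaluation of the method used a slightly stricter peak
#' threshold than the 0.3 sigma default; this preset returns it.
#' @return 0.35 (sigma units).
#' @export
paperEvalThreshold <- function() 0.35

#' Normalize peak areas within each chi trace of a residue
#'
#' Sets \code{relative_area} = area / (sum of areas of peaks on the same chi
#' trace of the same residue), so relative areas sum to 1 per chi per
#' residue.  These relative areas seed conformer occupancies.
#'
#' @param peaks data.frame from \code{\link{findDensityPeaks}} (rows may
#'   span several residues and chi traces).
#' @return The same data.frame with a \code{relative_area} column.
#' @export
normalizePeakAreas <- function(peaks) {
  if (nrow(peaks) == 0L) {
    peaks$relative_area <- numeric(0)
    return(peaks)
  }
  if (any(peaks$area <= 0)) stop("peak areas must be positive")
  key <- paste(peaks$chain, peaks$resno, peaks$insert, peaks$chi, sep = "|")
  tot <- tapply(peaks$area, key, sum)
  peaks$relative_area <- peaks$area / as.numeric(tot[key])
  peaks
}
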