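# Assemble detected peak angles across a residue's dihedrals into candidate
# rotamers, validate each combination against the ideal rotamer library
# within an angular tolerance, and name the survivors.
#
# A residue with two dihedrals and two peaks per dihedral yields up to four
# candidate combinations, but (when all match) never fewer than two named
# rotamers.  Among several library entries within tolerance the most
# frequent in the PDB is selected.  Candidates mapping to the same rotamer
# name collapse to the one with the best geometry (smallest maximum
# deviation), and the output is ordered for building: largest density
# support first.

#' Enumerate peak-angle combinations for one residue
#'
#' Forms the full Cartesian product of per-chi peak choices.  Every chi of
#' the residue must carry at least one detected peak; callers skip residues
#' that do not (with a logged reason).
#'
#' @param peaksByChi List of per-chi peak data.frames (as returned by
#'   \code{\link{findDensityPeaks}} and \code{\link{normalizePeakAreas}}),
#'   one element per chi in chi order.
#' @return data.frame with one row per combination: columns
#'   \code{chi1..chiN} (peak angles, degrees), \code{support} (the minimum
#'   contributing peak height, sigma) and \code{peak1..peakN} (row index of
#'   the chosen peak per chi).
#' @export
enumerateCombinations <- function(peaksByChi) {
  n <- length(peaksByChi)
  counts <- vapply(peaksByChi, nrow, integer(1))
  if (any(counts == 0L))
    stop("every chi must have at least one detected peak (chi ",
         paste(which(counts == 0L), collapse = ", "), " has none)")
  idx <- do.call(expand.grid, lapply(counts, seq_len))
  names(idx) <- paste0("peak", seq_len(n))
  out <- idx
  for (k in seq_len(n)) {
    out[[paste0("chi", k)]] <- peaksByChi[[k]]$angle[idx[[k]]]
  }
  out$support <- do.call(pmin, lapply(seq_len(n), function(k)
    peaksByChi[[k]]$height[idx[[k]]]))
  out[, c(paste0("chi", seq_len(n)), "support", paste0("peak", seq_len(n))),
      drop = FALSE]
}

#' Match one chi-angle combination against the rotamer library
#'
#' A candidate matches an entry iff for every chi the circular deviation
#' between peak angle and modal angle is at most \code{tolerance} (with a
#' 180-degree period for the chemically symmetric terminal dihedrals of ASP,
#' GLU, PHE and TYR).  Among multiple matching entries the one most frequent
#' in the PDB is selected; frequency ties break lexicographically by name
#' for determinism.
#'
#' @param angles Numeric vector of candidate chi angles (deg), length nChi.
#' @param residueType Three-letter code.
#' @param library Rotamer library data.frame.
#' @param tolerance Maximum per-chi deviation in degrees (default 30).
#' @return \code{NULL} if no entry matches, else a list with \code{name},
#'   \code{maxDeviation} and \code{entry} (the library row).
#' @export
matchToLibrary <- function(angles, residueType, library, tolerance = 30) {
  stopifnot(tolerance > 0)
  entries <- rotamersFor(library, residueType)
  if (nrow(entries) == 0L)
    stop("unsupported residue type in library: ", residueType)
  n <- nChi(residueType)
  stopifnot(length(angles) == n)
  periods <- vapply(seq_len(n), function(k) chiPeriod(residueType, k),
                    numeric(1))
  dev <- matrix(NA_real_, nrow = nrow(entries), ncol = n)
  for (k in seq_len(n)) {
    dev[, k] <- circularDiff(angles[k], entries[[paste0("chi", k)]],
                             period = periods[k])
  }
  maxDev <- apply(dev, 1L, max)
  ok <- maxDev <= tolerance
  if (!any(ok)) return(NULL)
  hits <- entries[ok, , drop = FALSE]
  hits$maxDev <- maxDev[ok]
  hits <- hits[order(-hits$frequency, hits$rotamer_name), , drop = FALSE]
  list(name = hits$rotamer_name[1L], maxDeviation = hits$maxDev[1L],
       entry = hits[1L, , drop = FALSE])
}

#' Assemble, validate and name candidate rotamers for one residue
#'
#' Runs \code{\link{enumerateCombinations}}, matches every combination via
#' \code{\link{matchToLibrary}}, collapses candidates sharing a rotamer name
#' (keeping the best geometry) and orders the result for building: largest
#' density support first, ties broken lexicographically by name.  If the
#' current (input-model) conformation is supplied, the library entry it
#' matches is flagged \code{isOriginal} so building can retain it as
#' conformer A rather than duplicating it.
#'
#' The \code{seedRelativeArea} of each candidate is the relative peak area
#' of its chosen peak on the occupancy-attribution chi: the first chi (from
#' chi1 outward) that carries more than one peak.  These areas seed
#' conformer occupancies downstream.
#'
#' @param peaksByChi List of per-chi peak data.frames (with
#'   \code{relative_area}), one element per chi.
#' @param residueType Three-letter code.
#' @param library Rotamer library.
#' @param tolerance Maximum per-chi deviation (deg, default 30).
#' @param currentChi Optional measured chi angles of the input conformer.
#' @return data.frame with one row per named rotamer: \code{restype,
#'   rotamer, chi1..chiN} (contributing peak angles), \code{maxDeviation,
#'   support, seedRelativeArea, isOriginal}.  Zero rows when no combination
#'   survives.
#' @export
assembleRotamers <- function(peaksByChi, residueType, library,
                             tolerance = 30, currentChi = NULL) {
  n <- nChi(residueType)
  stopifnot(length(peaksByChi) == n)
  combos <- enumerateCombinations(peaksByChi)
  attribChi <- 1L
  multi <- which(vapply(peaksByChi, nrow, integer(1)) > 1L)
  if (length(multi) > 0L) attribChi <- multi[1L]

  rows <- list()
  for (i in seq_len(nrow(combos))) {
    angles <- as.numeric(combos[i, paste0("chi", seq_len(n))])
    hit <- matchToLibrary(angles, residueType, library, tolerance)
    if (is.null(hit)) next
    seedArea <- peaksByChi[[attribChi]]$relative_area[
      combos[[paste0("peak", attribChi)]][i]]
    if (is.null(seedArea)) seedArea <- NA_real_
    row <- data.frame(restype = residueType, rotamer = hit$name,
                      maxDeviation = hit$maxDeviation,
                      support = combos$support[i],
                      seedRelativeArea = seedArea,
                      stringsAsFactors = FALSE)
    for (k in seq_len(n)) row[[paste0("chi", k)]] <- angles[k]
    rows[[length(rows) + 1L]] <- row
  }
  cols <- c("restype", "rotamer", paste0("chi", seq_len(n)),
            "maxDeviation", "support", "seedRelativeArea", "isOriginal")
  if (length(rows) == 0L) {
    out <- data.frame(restype = character(0), rotamer = character(0),
                      maxDeviation = numeric(0), support = numeric(0),
                      seedRelativeArea = numeric(0),
                      isOriginal = logical(0))
    for (k in seq_len(n)) out[[paste0("chi", k)]] <- numeric(0)
    return(out[, cols])
  }
  cand <- do.call(rbind, rows)
  # collapse duplicates: keep the smallest max deviation per rotamer name
  cand <- cand[order(cand$rotamer, cand$maxDeviation, -cand$support), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand$rotamer), , drop = FALSE]
  # flag the input model's own rotamer (matched for naming only)
  cand$isOriginal <- FALSE
  if (!is.null(currentChi)) {
    orig <- matchToLibrary(currentChi, residueType, library, tolerance)
    if (!is.null(orig)) cand$isOriginal <- cand$rotamer == orig$name
  }
  cand <- cand[order(-cand$support, cand$rotamer), , drop = FALSE]
  rownames(cand) <- NULL
  cand[, cols]
}
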