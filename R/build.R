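# Multi-conformer model building: generate alternate side-chain conformers
# for named rotamers, assign altloc labels and seed occupancies, prune
# near-zero conformers, and validate with normalized B factors and
# real-space correlation.
#
# The original conformation always becomes altloc A; additional rotamers
# take the following letters in build order (largest density support
# first), so lower alphabetic labels correspond to the stronger density.
# New conformer geometry is generated by rigid rotation of each chi's
# rotating set onto the matched library entry's modal angles (bond lengths
# and angles untouched); a flag allows building at the measured peak angles
# instead.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Rotate the rotating set of chi k so the dihedral equals targetAngle.
rotateResidueChi <- function(coords, residueType, chiIndex, targetAngle) {
  def <- chiDefinitions(residueType)[[chiIndex]]
  quad <- def$atomQuadruple
  p <- coords[quad, , drop = FALSE]
  current <- measureDihedral(p[1L, ], p[2L, ], p[3L, ], p[4L, ])
  moving <- intersect(def$rotatingSet, rownames(coords))
  coords[moving, ] <- rotateAboutAxis(coords[moving, , drop = FALSE],
                                      origin = p[3L, ],
                                      axis = p[3L, ] - p[2L, ],
                                      deg = targetAngle - current)
  coords
}

#' Build alternate conformers into a residue
#'
#' Converts the residue's single conformation into altloc A and adds one
#' conformer per non-original rotamer, labelled B, C, ... in the given
#' order.  In \code{"full"} mode the whole residue including backbone atoms
#' is duplicated per conformer (backbone coordinates initially identical;
#' refinement separates them); in \code{"calpha"} mode the backbone keeps a
#' single blank-altloc copy at occupancy 1 and only the side chain (CB
#' outward) is duplicated.  B factors are copied from the source atoms.
#'
#' @param model A \code{MultiConformerModel}; the residue must currently be
#'   single-conformer (strip altlocs first).
#' @param chain,resno,insert Residue to build.
#' @param rotamers data.frame from \code{\link{assembleRotamers}} (rows with
#'   \code{isOriginal = TRUE} are retained as conformer A, not rebuilt).
#' @param library Rotamer library (for the modal target angles).
#' @param mode \code{"full"} (entire residue, the evaluation default) or
#'   \code{"calpha"} (branch at the C-alpha atom).
#' @param atMeasuredAngles Build at the measured peak angles instead of the
#'   library modal angles.
#' @return The modified \code{MultiConformerModel}.
#' @export
buildConformers <- function(model, chain, resno, insert = "", rotamers,
                            library = loadRotamerLibrary(),
                            mode = c("full", "calpha"),
                            atMeasuredAngles = FALSE) {
  mode <- match.arg(mode)
  at <- model@atoms
  sel <- which(at$chain == chain & at$resno == resno & at$insert == insert)
  if (length(sel) == 0L) stop("residue ", chain, " ", resno, " not found")
  restype <- at$resid[sel][1L]
  if (nrow(rotamers) > 0L && any(rotamers$restype != restype))
    stop("rotamers are for residue type ", rotamers$restype[1L],
         " but the residue is ", restype)
  newRot <- rotamers[!rotamers$isOriginal, , drop = FALSE]
  if (nrow(newRot) == 0L) return(model)
  if (any(at$alt[sel] != ""))
    stop("residue already carries altlocs; strip them before building")
  nconf <- 1L + nrow(newRot)
  if (nconf > 25L)
    stop("cannot build ", nconf, " conformers: altloc alphabet exhausted")

  resRows <- at[sel, , drop = FALSE]
  coords0 <- as.matrix(resRows[, c("x", "y", "z")])
  rownames(coords0) <- resRows$elety
  n <- nChi(restype)
  sidechain <- !resRows$elety %in% .BACKBONE_ATOMS

  blocks <- list()
  # conformer A: the original, never moved
  aRows <- resRows
  if (mode == "full") aRows$alt <- "A" else aRows$alt[sidechain] <- "A"
  blocks[[1L]] <- aRows

  entries <- rotamersFor(library, restype)
  for (j in seq_len(nrow(newRot))) {
    target <- if (atMeasuredAngles) {
      as.numeric(newRot[j, paste0("chi", seq_len(n))])
    } else {
      hit <- entries[entries$rotamer_name == newRot$rotamer[j], , drop = FALSE]
      if (nrow(hit) == 0L)
        stop("rotamer '", newRot$rotamer[j], "' not in library for ", restype)
      modalAngles(hit)
    }
    coords <- coords0
    for (k in seq_len(n)) coords <- rotateResidueChi(coords, restype, k,
                                                     target[k])
    rows <- resRows
    rows[, c("x", "y", "z")] <- coords[rows$elety, , drop = FALSE]
    rows$alt <- LETTERS[j + 1L]
    if (mode == "calpha") rows <- rows[sidechain, , drop = FALSE]
    blocks[[j + 1L]] <- rows
  }
  newRes <- do.call(rbind, blocks)
  before <- at[seq_len(min(sel) - 1L), , drop = FALSE]
  after <- if (max(sel) < nrow(at)) at[(max(sel) + 1L):nrow(at), , drop = FALSE]
           else at[0L, , drop = FALSE]
  MultiConformerModel(rbind(before, newRes, after), title = model@title)
}

#' Assign seed occupancies to a residue's conformers
#'
#' Area-weighted seeding sets each conformer's occupancy to its relative
#' electron-density peak area (renormalized over the residue's conformers);
#' uniform seeding gives 1/n each.  Occupancies are rounded to two decimals
#' (the PDB column convention) with the rounding remainder added to
#' conformer A so the per-residue sum is exactly 1.00.  These are seed
#' values only; refinement estimates the final occupancies.
#'
#' @param model A \code{MultiConformerModel}.
#' @param chain,resno,insert Residue.
#' @param scheme \code{"area"} or \code{"uniform"}.
#' @param seedAreas Named numeric vector (names = altloc labels) of relative
#'   areas; required for the area scheme.  Missing or NA areas fall back to
#'   uniform with a warning.
#' @return The model with occupancies set on the residue's altloc atoms.
#' @export
assignOccupancies <- function(model, chain, resno, insert = "",
                              scheme = c("area", "uniform"),
                              seedAreas = NULL) {
  scheme <- match.arg(scheme)
  alts <- residueAltlocs(model, chain, resno, insert)
  if (length(alts) == 0L) return(model)
  occ <- NULL
  if (scheme == "area") {
    if (is.null(seedAreas) || !all(alts %in% names(seedAreas)) ||
        any(is.na(seedAreas[alts]))) {
      warning("missing peak areas for residue ", chain, " ", resno,
              "; falling back to uniform occupancies")
    } else {
      occ <- as.numeric(seedAreas[alts])
      occ <- occ / sum(occ)
    }
  }
  if (is.null(occ)) occ <- rep(1 / length(alts), length(alts))
  occ <- round(occ, 2)
  occ[1L] <- round(occ[1L] + (1 - sum(occ)), 2)
  at <- model@atoms
  for (i in seq_along(alts)) {
    rows <- at$chain == chain & at$resno == resno & at$insert == insert &
      at$alt == alts[i]
    at$o[rows] <- occ[i]
  }
  MultiConformerModel(at, title = model@title)
}

#' Remove near-zero-occupancy conformers
#'
#' Conformers below the occupancy floor are removed and the survivors'
#' occupancies renormalized per residue (two decimals, remainder to the
#' first surviving conformer).  A residue reduced to a single conformer
#' loses its altloc labels.  Removing zero-occupancy conformers before the
#' final refinement avoids occupancy-refinement and bulk-solvent artefacts.
#'
#' @param model A \code{MultiConformerModel}.
#' @param minOccupancy Occupancy floor (default 0.01).
#' @return The pruned model.
#' @export
pruneLowOccupancy <- function(model, minOccupancy = 0.01) {
  at <- model@atoms
  keyv <- residueKey(at)
  drop <- rep(FALSE, nrow(at))
  for (key in unique(keyv[at$alt != ""])) {
    rows <- which(keyv == key)
    alts <- sort(unique(at$alt[rows][at$alt[rows] != ""]))
    occ <- vapply(alts, function(l) at$o[rows[at$alt[rows] == l]][1L],
                  numeric(1))
    keep <- occ >= minOccupancy
    if (!any(keep)) {
      warning("pruning would delete every conformer of residue ", key,
              "; keeping the highest-occupancy one")
      keep[which.max(occ)] <- TRUE
    }
    if (all(keep)) next
    drop[rows[at$alt[rows] %in% alts[!keep]]] <- TRUE
    newOcc <- occ[keep] / sum(occ[keep])
    newOcc <- round(newOcc, 2)
    newOcc[1L] <- round(newOcc[1L] + (1 - sum(newOcc)), 2)
    survivors <- alts[keep]
    if (length(survivors) == 1L) {
      r <- rows[at$alt[rows] == survivors]
      at$alt[r] <- ""
      at$o[r] <- 1
    } else {
      for (i in seq_along(survivors)) {
        r <- rows[at$alt[rows] == survivors[i]]
        at$o[r] <- newOcc[i]
      }
    }
  }
  MultiConformerModel(at[!drop, , drop = FALSE], title = model@title)
}

#' Normalized B factors
#'
#' Computes B_norm = (B - mean(B)) / sd(B) per atom, with the mean and
#' standard deviation taken over all protein (ATOM) atoms of the model.
#' The population standard deviation is the default.
#'
#' @param model A \code{MultiConformerModel}.
#' @param sdType \code{"population"} (default) or \code{"sample"}.
#' @return Numeric vector of B_norm values, one per protein atom (in atom
#'   order).
#' @export
bNorm <- function(model, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  b <- model@atoms$b[model@atoms$type == "ATOM"]
  if (length(b) < 2L) stop("need at least two protein atoms with B factors")
  m <- mean(b)
  s <- if (sdType == "population") sqrt(mean((b - m)^2)) else stats::sd(b)
  if (s == 0) stop("all B factors identical: zero standard deviation")
  (b - m) / s
}

#' Real-space correlation coefficient
#'
#' Pearson correlation between observed (sigma-scaled) map values and the
#' model-computed Gaussian-atom density, over all grid points within
#' \code{radius} of any selected atom (periodic P1).
#'
#' @param map A sigma-scaled \code{DensityMap} covering the full cell.
#' @param model A \code{MultiConformerModel} (all atoms contribute to the
#'   calculated density).
#' @param selection Integer or logical index into the atom table choosing
#'   the atoms whose neighbourhood is evaluated.
#' @param radius Mask radius in angstrom (default 2.0).
#' @return The RSCC (in [-1, 1]).
#' @export
rscc <- function(map, model, selection, radius = 2.0) {
  if (!isSigmaScaled(map)) stop("map must be sigma-scaled")
  at <- model@atoms
  selAtoms <- at[selection, , drop = FALSE]
  if (nrow(selAtoms) == 0L) stop("empty atom selection")
  n <- map@gridShape
  cell <- map@cell
  M <- orthoMatrix(cell)
  nodes <- matrix(integer(0), ncol = 3L)
  for (i in seq_len(nrow(selAtoms))) {
    fa <- cartToFrac(c(selAtoms$x[i], selAtoms$y[i], selAtoms$z[i]), cell)
    half <- ceiling(radius * n / cell[1:3]) + 1L
    ctr <- round(fa * n)
    off <- as.matrix(expand.grid(-half[1L]:half[1L], -half[2L]:half[2L],
                                 -half[3L]:half[3L]))
    cand <- sweep(off, 2L, ctr, `+`)
    df <- sweep(sweep(cand, 2L, n, `/`), 2L, fa)
    df <- df - round(df)
    d <- t(M %*% t(df))
    keep <- rowSums(d * d) <= radius^2
    nodes <- rbind(nodes, cand[keep, , drop = FALSE])
  }
  nodes <- unique(nodes %% matrix(n, nrow = nrow(nodes), ncol = 3L,
                                  byrow = TRUE))
  if (nrow(nodes) < 10L)
    stop("selection too small: fewer than 10 grid points in the mask")
  observed <- map@grid[nodes + 1L]
  xyz <- fracToCart(sweep(nodes, 2L, n, `/`), cell)
  calc <- gaussianDensityAt(at, xyz, cell)
  stats::cor(observed, calc)
}

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Report steric clashes between alternate conformers and their surroundings
#'
#' Flags pairs of heavy atoms in different residues whose distance falls
#' more than \code{tolerance} below the sum of their van der Waals radii and
#' whose altloc labels can coexist (equal labels, or either blank).  The
#' peptide-bond C(i)-N(i+1) contact is ignored.  Informational only: clashes
#' never block building, and waters are never moved or deleted; inspect the
#' report instead.
#'
#' @param model A \code{MultiConformerModel}.
#' @param tolerance Allowed overlap in angstrom before a pair is flagged
#'   (default 0.4).
#' @return data.frame of clashing pairs with distances and overlaps.
#' @export
clashReport <- function(model, tolerance = 0.4) {
  at <- model@atoms
  r <- .VDW_RADII[at$elesy]
  r[is.na(r)] <- 1.7
  xyz <- as.matrix(at[, c("x", "y", "z")])
  key <- residueKey(at)
  out <- list()
  nb <- nrow(at)
  if (nb > 1L) {
    dmat <- as.matrix(stats::dist(xyz))
    lim <- outer(r, r, `+`) - tolerance
    hit <- which(dmat < lim & upper.tri(dmat), arr.ind = TRUE)
    for (h in seq_len(nrow(hit))) {
      i <- hit[h, 1L]; j <- hit[h, 2L]
      if (key[i] == key[j]) next
      ai <- at$alt[i]; aj <- at$alt[j]
      if (ai != "" && aj != "" && ai != aj) next
      peptide <- at$chain[i] == at$chain[j] &&
        abs(at$resno[i] - at$resno[j]) == 1L &&
        ((at$elety[i] == "C" && at$elety[j] == "N") ||
           (at$elety[i] == "N" && at$elety[j] == "C"))
      if (peptide) next
      out[[length(out) + 1L]] <- data.frame(
        chain1 = at$chain[i], resno1 = at$resno[i], atom1 = at$elety[i],
        alt1 = ai, chain2 = at$chain[j], resno2 = at$resno[j],
        atom2 = at$elety[j], alt2 = aj,
        distance = dmat[i, j], overlap = lim[i, j] + tolerance - dmat[i, j])
    }
  }
  if (length(out) == 0L)
    return(data.frame(chain1 = character(0), resno1 = integer(0),
                      atom1 = character(0), alt1 = character(0),
                      chain2 = character(0), resno2 = integer(0),
                      atom2 = character(0), alt2 = character(0),
                      distance = numeric(0), overlap = numeric(0)))
  do.call(rbind, out)
}
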