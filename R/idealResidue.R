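# Internal-coordinate templates for building ideal residues.
#
# Each side-chain atom is placed by the NeRF construction from three
# reference atoms with a bond length (angstrom), bond angle (deg) and a
# torsion that is either fixed or a chi angle plus a branch offset.  Bond
# lengths and angles are standard protein values; rings are closed by fixed
# planar torsions.  Only heavy atoms are modelled (hydrogens are ignored
# throughout the package).

.chiTors <- function(k, offset = 0) list(chi = k, offset = offset)

.sc <- function(atom, a, b, c, bond, angle, tors) {
  list(atom = atom, ref = c(a, b, c), bond = bond, angle = angle, tors = tors)
}

.SIDECHAIN_TEMPLATES <- list(
  SER = list(.sc("OG", "N", "CA", "CB", 1.417, 110.8, .chiTors(1))),
  CYS = list(.sc("SG", "N", "CA", "CB", 1.808, 113.8, .chiTors(1))),
  THR = list(.sc("OG1", "N", "CA", "CB", 1.433, 109.6, .chiTors(1)),
             .sc("CG2", "N", "CA", "CB", 1.521, 110.5, .chiTors(1, -120))),
  VAL = list(.sc("CG1", "N", "CA", "CB", 1.527, 110.5, .chiTors(1)),
             .sc("CG2", "N", "CA", "CB", 1.527, 110.5, .chiTors(1, 122))),
  LEU = list(.sc("CG", "N", "CA", "CB", 1.530, 116.3, .chiTors(1)),
             .sc("CD1", "CA", "CB", "CG", 1.524, 110.7, .chiTors(2)),
             .sc("CD2", "CA", "CB", "CG", 1.525, 110.4, .chiTors(2, 122))),
  ILE = list(.sc("CG1", "N", "CA", "CB", 1.530, 110.4, .chiTors(1)),
             .sc("CG2", "N", "CA", "CB", 1.521, 110.5, .chiTors(1, -122)),
             .sc("CD1", "CA", "CB", "CG1", 1.513, 113.8, .chiTors(2))),
  MET = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chiTors(1)),
             .sc("SD", "CA", "CB", "CG", 1.803, 112.7, .chiTors(2)),
             .sc("CE", "CB", "CG", "SD", 1.791, 100.9, .chiTors(3))),
  ASP = list(.sc("CG", "N", "CA", "CB", 1.516, 112.6, .chiTors(1)),
             .sc("OD1", "CA", "CB", "CG", 1.249, 118.4, .chiTors(2)),
             .sc("OD2", "CA", "CB", "CG", 1.249, 118.4, .chiTors(2, 180))),
  ASN = list(.sc("CG", "N", "CA", "CB", 1.516, 112.6, .chiTors(1)),
             .sc("OD1", "CA", "CB", "CG", 1.231, 120.8, .chiTors(2)),
             .sc("ND2", "CA", "CB", "CG", 1.328, 116.4, .chiTors(2, 180))),
  GLU = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chiTors(1)),
             .sc("CD", "CA", "CB", "CG", 1.516, 112.6, .chiTors(2)),
             .sc("OE1", "CB", "CG", "CD", 1.249, 118.4, .chiTors(3)),
             .sc("OE2", "CB", "CG", "CD", 1.249, 118.4, .chiTors(3, 180))),
  GLN = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chiTors(1)),
             .sc("CD", "CA", "CB", "CG", 1.516, 112.6, .chiTors(2)),
             .sc("OE1", "CB", "CG", "CD", 1.231, 120.8, .chiTors(3)),
             .sc("NE2", "CB", "CG", "CD", 1.328, 116.4, .chiTors(3, 180))),
  LYS = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chiTors(1)),
             .sc("CD", "CA", "CB", "CG", 1.520, 111.3, .chiTors(2)),
             .sc("CE", "CB", "CG", "CD", 1.520, 111.3, .chiTors(3)),
             .sc("NZ", "CG", "CD", "CE", 1.489, 111.9, .chiTors(4))),
  ARG = list(.sc("CG", "N", "CA", "CB", 1.520, 114.1, .chiTors(1)),
             .sc("CD", "CA", "CB", "CG", 1.520, 111.3, .chiTors(2)),
             .sc("NE", "CB", "CG", "CD", 1.461, 112.0, .chiTors(3)),
             .sc("CZ", "CG", "CD", "NE", 1.329, 124.2, .chiTors(4)),
             .sc("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             .sc("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  HIS = list(.sc("CG", "N", "CA", "CB", 1.497, 113.8, .chiTors(1)),
             .sc("ND1", "CA", "CB", "CG", 1.378, 122.7, .chiTors(2)),
             .sc("CD2", "CA", "CB", "CG", 1.354, 131.2, .chiTors(2, 180)),
             .sc("CE1", "CB", "CG", "ND1", 1.321, 109.3, 180),
             .sc("NE2", "CG", "ND1", "CE1", 1.321, 111.7, 0)),
  PHE = list(.sc("CG", "N", "CA", "CB", 1.502, 113.8, .chiTors(1)),
             .sc("CD1", "CA", "CB", "CG", 1.384, 120.8, .chiTors(2)),
             .sc("CD2", "CA", "CB", "CG", 1.384, 120.8, .chiTors(2, 180)),
             .sc("CE1", "CB", "CG", "CD1", 1.384, 120.8, 180),
             .sc("CE2", "CB", "CG", "CD2", 1.384, 120.8, 180),
             .sc("CZ", "CG", "CD1", "CE1", 1.382, 120.1, 0)),
  TYR = list(.sc("CG", "N", "CA", "CB", 1.502, 113.8, .chiTors(1)),
             .sc("CD1", "CA", "CB", "CG", 1.384, 120.8, .chiTors(2)),
             .sc("CD2", "CA", "CB", "CG", 1.384, 120.8, .chiTors(2, 180)),
             .sc("CE1", "CB", "CG", "CD1", 1.384, 120.8, 180),
             .sc("CE2", "CB", "CG", "CD2", 1.384, 120.8, 180),
             .sc("CZ", "CG", "CD1", "CE1", 1.382, 120.1, 0),
             .sc("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = list(.sc("CG", "N", "CA", "CB", 1.498, 113.6, .chiTors(1)),
             .sc("CD1", "CA", "CB", "CG", 1.365, 126.9, .chiTors(2)),
             .sc("CD2", "CA", "CB", "CG", 1.433, 126.8, .chiTors(2, 180)),
             .sc("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
             .sc("CE2", "CG", "CD1", "NE1", 1.370, 108.9, 0),
             .sc("CE3", "CB", "CG", "CD2", 1.398, 130.6, 0),
             .sc("CZ2", "CD1", "NE1", "CE2", 1.394, 130.1, 180),
             .sc("CZ3", "CG", "CD2", "CE3", 1.391, 118.7, 180),
             .sc("CH2", "CD2", "CE3", "CZ3", 1.368, 121.1, 0))
)

# Element symbol of a heavy-atom PDB name (single-letter elements only).
atomElement <- function(atomName) substr(atomName, 1L, 1L)

#' Build an ideal residue conformer
#'
#' Constructs one residue with standard bond lengths and angles, the side
#' chain set either to the modal chi angles of a named rotamer-library entry
#' or to explicitly given chi angles.  The backbone (N, CA, C, O) lies in a
#' canonical local frame; use \code{center} to translate the residue (by its
#' CA atom) to a position inside a unit cell.
#'
#' @param residueType Three-letter code (GLY/ALA/PRO are rejected: they have
#'   no rotamers to build).
#' @param rotamerName Name of a library entry (e.g. \code{"p"}); ignored when
#'   \code{chiAngles} is given.
#' @param library Rotamer library data.frame (default: bundled library).
#' @param chiAngles Optional numeric vector of chi angles (deg) overriding
#'   the library entry.
#' @param center Optional length-3 Cartesian target for the CA atom.
#' @return Numeric coordinate matrix (rows = atoms, named) with an
#'   \code{"element"} attribute.
#' @examples
#' xyz <- buildIdealResidue("THR", "p")
#' measureChi(xyz, "THR", 1)  # ~62
#' @export
buildIdealResidue <- function(residueType, rotamerName = NULL,
                              library = loadRotamerLibrary(),
                              chiAngles = NULL, center = NULL) {
  residueType <- toupper(residueType)
  n <- nChi(residueType)
  if (n == 0L)
    stop("residue type ", residueType, " has no rotamers to build")
  if (is.null(chiAngles)) {
    entries <- rotamersFor(library, residueType)
    if (is.null(rotamerName))
      stop("supply rotamerName or chiAngles for ", residueType)
    hit <- entries[entries$rotamer_name == rotamerName, , drop = FALSE]
    if (nrow(hit) == 0L)
      stop("unknown rotamer name '", rotamerName, "' for ", residueType,
           "; valid names: ", paste(entries$rotamer_name, collapse = ", "))
    chiAngles <- modalAngles(hit)
  }
  if (length(chiAngles) != n)
    stop("expected ", n, " chi angles for ", residueType)

  # canonical backbone frame
  coords <- matrix(NA_real_, nrow = 0L, ncol = 3L)
  addAtom <- function(name, xyz) {
    coords <<- rbind(coords, matrix(xyz, nrow = 1L,
                                    dimnames = list(name, NULL)))
  }
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  angNCAC <- 111.2 * pi / 180
  C <- CA + 1.525 * c(-cos(angNCAC), sin(angNCAC), 0)
  addAtom("N", N)
  addAtom("CA", CA)
  addAtom("C", C)
  addAtom("O", placeAtom(N, CA, C, 1.231, 120.5, 0))
  addAtom("CB", placeAtom(N, C, CA, 1.530, 110.1, 122.5))

  for (e in .SIDECHAIN_TEMPLATES[[residueType]]) {
    tors <- if (is.list(e$tors)) {
      wrap180(chiAngles[e$tors$chi] + e$tors$offset)
    } else {
      e$tors
    }
    ref <- coords[e$ref, , drop = FALSE]
    addAtom(e$atom, placeAtom(ref[1L, ], ref[2L, ], ref[3L, ],
                              e$bond, e$angle, tors))
  }
  if (!is.null(center))
    coords <- sweep(coords, 2L, coords["CA", ] - center)
  attr(coords, "element") <- atomElement(rownames(coords))
  coords
}
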