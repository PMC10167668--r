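# Side-chain dihedral (chi) definitions and the ideal rotamer library.
#
# Chi quadruples follow the standard chi1..chi4 conventions (chi1 = N-CA-CB-CG
# etc.).  The "rotating set" of chi n is every side-chain atom distal to the
# rotating bond, so rotating_set(chi n) is a strict superset of
# rotating_set(chi n+1).  GLY and ALA have no chi angles; PRO formally has
# chi1/chi2 but its ring constrains them, so PRO is excluded from sampling and
# building throughout.

.CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

.CHI_ROTATING <- list(
  ARG = list(c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
             c("CD", "NE", "CZ", "NH1", "NH2"),
             c("NE", "CZ", "NH1", "NH2"),
             c("CZ", "NH1", "NH2")),
  ASN = list(c("CG", "OD1", "ND2"), c("OD1", "ND2")),
  ASP = list(c("CG", "OD1", "OD2"), c("OD1", "OD2")),
  CYS = list(c("SG")),
  GLN = list(c("CG", "CD", "OE1", "NE2"), c("CD", "OE1", "NE2"),
             c("OE1", "NE2")),
  GLU = list(c("CG", "CD", "OE1", "OE2"), c("CD", "OE1", "OE2"),
             c("OE1", "OE2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"),
             c("ND1", "CD2", "CE1", "NE2")),
  ILE = list(c("CG1", "CG2", "CD1"), c("CD1")),
  LEU = list(c("CG", "CD1", "CD2"), c("CD1", "CD2")),
  LYS = list(c("CG", "CD", "CE", "NZ"), c("CD", "CE", "NZ"),
             c("CE", "NZ"), c("NZ")),
  MET = list(c("CG", "SD", "CE"), c("SD", "CE"), c("CE")),
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             c("CD1", "CD2", "CE1", "CE2", "CZ")),
  SER = list(c("OG")),
  THR = list(c("OG1", "CG2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
             c("CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
             c("CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
  VAL = list(c("CG1", "CG2"))
)

# Terminal dihedrals that are chemically 180 degree-periodic: the two branch
# atoms are indistinguishable, so library matching uses a 180 degree period.
.SYMMETRIC_CHI <- c(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L)

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# Residue types eligible for sampling and building.
.ELIGIBLE_AA <- setdiff(names(.CHI_ATOMS), character(0))

#' Chi dihedral definitions for a residue type
#'
#' Returns the ordered chi1..chiN dihedral definitions of a standard amino
#' acid: the four atom names defining each dihedral and the set of side-chain
#' atoms that move when that chi rotates.  GLY and ALA return an empty list;
#' PRO also returns an empty list because its pyrrolidine ring constrains the
#' chi angles and the method does not sample or rebuild proline.
#'
#' @param residueType Three-letter amino-acid code (e.g. \code{"SER"}).
#' @return A list of \code{ChiDefinition} objects, each a list with elements
#'   \code{residueType}, \code{chiIndex}, \code{atomQuadruple} (character-4)
#'   and \code{rotatingSet} (character vector).
#' @examples
#' chiDefinitions("SER")
#' length(chiDefinitions("LYS"))  # 4
#' @export
chiDefinitions <- function(residueType) {
  residueType <- toupper(residueType)
  if (!residueType %in% .STANDARD_AA)
    stop("unsupported residue type: ", residueType)
  if (residueType %in% c("GLY", "ALA", "PRO")) return(list())
  quads <- .CHI_ATOMS[[residueType]]
  rots <- .CHI_ROTATING[[residueType]]
  lapply(seq_along(quads), function(i) {
    structure(list(residueType = residueType,
                   chiIndex = i,
                   atomQuadruple = quads[[i]],
                   rotatingSet = rots[[i]]),
              class = "ChiDefinition")
  })
}

#' Number of chi angles of a residue type
#' @param residueType Three-letter amino-acid code.
#' @return Integer count of chi dihedrals (0 for GLY/ALA/PRO).
#' @export
nChi <- function(residueType) length(chiDefinitions(residueType))

#' Load the ideal rotamer library
#'
#' Reads a rotamer-library table (residue type, rotamer name, modal chi
#' angles, PDB frequency).  By default the copy bundled with the package is
#' used; it is derived from the published penultimate rotamer library of
#' ideal side-chain rotamers (modal angles and approximate relative PDB
#' frequencies).  Users can substitute any table with the same schema.
#'
#' @param source Path to a CSV with columns \code{residue_type},
#'   \code{rotamer_name}, \code{chi1}..\code{chi4} (blank where a residue has
#'   fewer dihedrals) and \code{frequency}.  \code{NULL} loads the bundled
#'   library.
#' @return A data.frame with one row per rotamer, columns as in the file,
#'   validated against the chi definitions (angle count per residue type,
#'   unique names, frequencies summing to at most 1 per residue type).
#' @examples
#' lib <- loadRotamerLibrary()
#' rotamersFor(lib, "THR")$rotamer_name  # "p" "t" "m"
#' @export
loadRotamerLibrary <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "rotamer_library.csv",
                          package = "flexbuild", mustWork = TRUE)
  lib <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("residue_type", "rotamer_name", "chi1", "chi2", "chi3", "chi4",
            "frequency")
  if (!all(need %in% names(lib)))
    stop("malformed rotamer library: missing columns ",
         paste(setdiff(need, names(lib)), collapse = ", "))
  lib$residue_type <- toupper(lib$residue_type)
  unknown <- !lib$residue_type %in% .STANDARD_AA
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " rotamer entries with unknown residue type: ",
            paste(unique(lib$residue_type[unknown]), collapse = ", "))
    lib <- lib[!unknown, , drop = FALSE]
  }
  for (i in seq_len(nrow(lib))) {
    rt <- lib$residue_type[i]
    n <- nChi(rt)
    if (n == 0L)
      stop("malformed rotamer library row ", i, ": residue type ", rt,
           " has no chi angles")
    angles <- as.numeric(lib[i, paste0("chi", seq_len(n))])
    if (any(!is.finite(angles)))
      stop("malformed rotamer library row ", i, ": expected ", n,
           " finite chi angles for ", rt)
    extra <- if (n < 4L) as.numeric(lib[i, paste0("chi", (n + 1L):4L)]) else numeric(0)
    if (any(is.finite(extra)))
      stop("malformed rotamer library row ", i, ": too many chi angles for ", rt)
  }
  if (any(lib$frequency < 0 | lib$frequency > 1))
    stop("malformed rotamer library: frequencies must lie in [0, 1]")
  bad <- tapply(lib$frequency, lib$residue_type, sum) > 1 + 1e-9
  if (any(bad))
    stop("malformed rotamer library: frequencies of ",
         paste(names(bad)[bad], collapse = ", "), " sum above 1")
  dup <- tapply(lib$rotamer_name, lib$residue_type,
                function(x) anyDuplicated(x) > 0L)
  if (any(dup))
    stop("malformed rotamer library: duplicated rotamer names for ",
         paste(names(dup)[dup], collapse = ", "))
  # normalize angles into [-180, 180)
  for (k in 1:4) lib[[paste0("chi", k)]] <- wrap180(lib[[paste0("chi", k)]])
  lib
}

#' Rotamer-library entries for one residue type
#' @param library Data.frame from \code{\link{loadRotamerLibrary}}.
#' @param residueType Three-letter code.
#' @return The matching rows (zero rows for GLY/ALA/PRO).
#' @export
rotamersFor <- function(library, residueType) {
  residueType <- toupper(residueType)
  library[library$residue_type == residueType, , drop = FALSE]
}

# Modal chi angles of one library entry as a numeric vector of length nChi.
modalAngles <- function(entry) {
  n <- nChi(entry$residue_type[1L])
  as.numeric(entry[1L, paste0("chi", seq_len(n))])
}

#' Measure a chi dihedral of a residue conformer
#'
#' @param coords Numeric matrix of atom coordinates with atom names as row
#'   names (one conformer of one residue).
#' @param residueType Three-letter code.
#' @param chiIndex Which chi (1-based).
#' @return Signed dihedral in degrees, \code{[-180, 180)}.
#' @export
measureChi <- function(coords, residueType, chiIndex) {
  defs <- chiDefinitions(residueType)
  if (chiIndex < 1L || chiIndex > length(defs))
    stop("residue type ", residueType, " has no chi", chiIndex)
  quad <- defs[[chiIndex]]$atomQuadruple
  missing <- setdiff(quad, rownames(coords))
  if (length(missing) > 0L)
    stop("incomplete side chain: ", residueType, " missing atom(s) ",
         paste(missing, collapse = ", "))
  p <- coords[quad, , drop = FALSE]
  if (any(!is.finite(p)))
    stop("incomplete side chain: non-finite coordinates in ", residueType)
  measureDihedral(p[1L, ], p[2L, ], p[3L, ], p[4L, ])
}

#' Measure all chi dihedrals of a residue conformer
#' @inheritParams measureChi
#' @return Numeric vector of length \code{nChi(residueType)}.
#' @export
measureAllChi <- function(coords, residueType) {
  n <- nChi(residueType)
  if (n == 0L) return(numeric(0))
  vapply(seq_len(n), function(k) measureChi(coords, residueType, k), numeric(1))
}

# Period (deg) used when comparing chi k of a residue type against the
# library: 180 for the chemically symmetric terminal dihedrals.
chiPeriod <- function(residueType, chiIndex) {
  sym <- .SYMMETRIC_CHI[residueType]
  if (!is.na(sym) && sym == chiIndex) 180 else 360
}
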