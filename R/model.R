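# The multi-conformer model container and its PDB/mmCIF input-output.
#
# Atoms live in a flat data.frame (one row per atom) in file order, with a
# one-character altloc label ("" = shared by all conformers) and an
# occupancy per atom.  PDB reading goes through bio3d; PDB writing uses
# bio3d's writer and the mmCIF writer is a minimal atom_site loop.

.ATOM_COLUMNS <- c("type", "eleno", "elety", "alt", "resid", "chain",
                   "resno", "insert", "x", "y", "z", "o", "b", "elesy")

#' MultiConformerModel: a protein model with altloc-labelled conformers
#'
#' @slot atoms data.frame, one row per atom, columns \code{type, eleno,
#'   elety, alt, resid, chain, resno, insert, x, y, z, o, b, elesy}.
#'   \code{alt} is \code{""} for atoms shared by all conformers.
#' @slot title Free-text header carried through reads and writes.
#' @export
setClass("MultiConformerModel",
         representation(atoms = "data.frame", title = "character"))

setValidity("MultiConformerModel", function(object) {
  msg <- character(0)
  miss <- setdiff(.ATOM_COLUMNS, names(object@atoms))
  if (length(miss) > 0L)
    msg <- c(msg, paste("atoms missing columns:", paste(miss, collapse = ", ")))
  if (length(msg) == 0L && nrow(object@atoms) > 0L) {
    if (any(!is.finite(object@atoms$x + object@atoms$y + object@atoms$z)))
      msg <- c(msg, "non-finite coordinates")
    if (any(object@atoms$o < 0 | object@atoms$o > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "occupancies must lie in [0, 1]")
    if (any(nchar(object@atoms$alt) > 1L))
      msg <- c(msg, "altloc labels must be single characters")
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Construct a MultiConformerModel from an atom table
#' @param atoms data.frame with the columns documented in the class.
#' @param title Optional header text.
#' @return A \code{MultiConformerModel}.
#' @export
MultiConformerModel <- function(atoms, title = "") {
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- "A"
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  rownames(atoms) <- NULL
  new("MultiConformerModel", atoms = atoms[, .ATOM_COLUMNS], title = title)
}

setMethod("show", "MultiConformerModel", function(object) {
  at <- object@atoms
  nres <- nrow(unique(at[at$type == "ATOM", c("chain", "resno", "insert")]))
  nalt <- length(unique(residueKey(at)[at$alt != ""]))
  cat(sprintf("MultiConformerModel: %d atoms, %d residues, %d with altlocs\n",
              nrow(at), nres, nalt))
})

#' @rdname modelAccessors
#' @name modelAccessors
#' @title MultiConformerModel accessors
#' @param model A \code{MultiConformerModel}.
#' @return \code{modelAtoms}: the atom data.frame.
#' @export
modelAtoms <- function(model) model@atoms

# "chain|resno|insert" key identifying a residue.
residueKey <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert,
                                    sep = "|")

#' Residues of a model
#' @param model A \code{MultiConformerModel}.
#' @param protein Restrict to ATOM records.
#' @return data.frame with one row per residue: chain, resno, insert, resid.
#' @export
residueTable <- function(model, protein = TRUE) {
  at <- model@atoms
  if (protein) at <- at[at$type == "ATOM", , drop = FALSE]
  out <- unique(at[, c("chain", "resno", "insert", "resid")])
  rownames(out) <- NULL
  out
}

#' Coordinates of one residue conformer
#'
#' @param model A \code{MultiConformerModel}.
#' @param chain,resno,insert Residue identifier.
#' @param alt Altloc label; atoms with blank altloc are always included, and
#'   \code{alt = ""} selects only blank-altloc atoms.
#' @return Numeric matrix with atom names as row names.
#' @export
residueCoords <- function(model, chain, resno, insert = "", alt = "") {
  at <- model@atoms
  sel <- at$chain == chain & at$resno == resno & at$insert == insert &
    (at$alt == "" | at$alt == alt)
  sub <- at[sel, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("residue ", chain, " ", resno, insert, " not found")
  # when both a blank and a labelled copy of an atom exist, keep the labelled
  sub <- sub[order(sub$elety, sub$alt != alt), ]
  sub <- sub[!duplicated(sub$elety), ]
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- sub$elety
  m
}

#' Altloc labels present for one residue
#' @param model A \code{MultiConformerModel}.
#' @param chain,resno,insert Residue identifier.
#' @return Sorted character vector of altloc labels (blank excluded; empty
#'   for single-conformer residues).
#' @export
residueAltlocs <- function(model, chain, resno, insert = "") {
  at <- model@atoms
  sel <- at$chain == chain & at$resno == resno & at$insert == insert &
    at$alt != ""
  sort(unique(at$alt[sel]))
}

#' Per-residue occupancy sums over alternate conformers
#'
#' For every residue carrying altloc labels, sums the occupancy of one
#' representative atom per conformer (conformer occupancies, not atom
#' counts).  A finished multi-conformer model sums to 1 per residue.
#'
#' @param model A \code{MultiConformerModel}.
#' @return Named numeric vector of sums, one per altloc-carrying residue.
#' @export
occupancySums <- function(model) {
  at <- model@atoms
  at <- at[at$alt != "", , drop = FALSE]
  if (nrow(at) == 0L) return(numeric(0))
  key <- residueKey(at)
  vapply(split(at, key), function(res) {
    sum(vapply(split(res$o, res$alt), function(x) x[1L], numeric(1)))
  }, numeric(1))
}

#' Read a model from PDB or mmCIF
#'
#' @param path Model file (\code{.pdb} or \code{.cif}).
#' @return A \code{MultiConformerModel}.
#' @export
readModel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path, verbose = FALSE,
                                           rm.alt = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  if (is.null(at$elesy) || all(is.na(at$elesy)))
    at$elesy <- atomElement(at$elety)
  MultiConformerModel(at[, .ATOM_COLUMNS], title = "")
}

#' Write a model to PDB or mmCIF
#'
#' Occupancies are written with two decimals (PDB column convention); a
#' read-back round trip preserves coordinates to format precision.
#'
#' @param model A \code{MultiConformerModel}.
#' @param path Output file.
#' @param format \code{"pdb"} or \code{"cif"} (default from the extension).
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path,
                       format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "cif") "cif" else "pdb"
  at <- model@atoms
  if (format == "pdb") {
    if (any(at$resno > 9999))
      stop("residue numbers exceed the PDB serial space; write mmCIF instead")
    if (nrow(at) > 99999)
      stop("atom count exceeds the PDB serial space; write mmCIF instead")
    alt <- at$alt
    alt[alt == ""] <- ""
    insert <- at$insert
    insert[insert == ""] <- ""
    bio3d::write.pdb(file = path,
                     type = at$type,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$resno, resid = at$resid, chain = at$chain,
                     insert = insert, alt = alt,
                     eleno = seq_len(nrow(at)), elety = at$elety,
                     o = round(at$o, 2), b = at$b, elesy = at$elesy)
  } else {
    writeCIF(model, path)
  }
  invisible(path)
}

# Minimal mmCIF atom_site writer (the canonical PDBx column set).
writeCIF <- function(model, path) {
  at <- model@atoms
  lines <- c("data_flexbuild",
             "#",
             "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
  alt <- ifelse(at$alt == "", ".", at$alt)
  ins <- ifelse(at$insert == "", "?", at$insert)
  rows <- sprintf(
    "%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    at$type, seq_len(nrow(at)), at$elesy, at$elety, alt, at$resid,
    at$chain, at$resno, ins, at$x, at$y, at$z, at$o, at$b,
    at$resno, at$resid, at$chain, at$elety)
  writeLines(c(lines, rows, "#"), path)
  invisible(path)
}

#' Reduce a model to single conformers
#'
#' Discards alternate conformations, keeping for each residue the conformer
#' with the highest occupancy (ties: the lowest altloc label), and resets
#' altloc labels to blank and occupancies to 1.  This mirrors the usual
#' practice of stripping deposited altlocs before multi-conformer building.
#'
#' @param model A \code{MultiConformerModel}.
#' @param keep Altloc to keep where present (\code{NULL} = highest occupancy).
#' @return A single-conformer \code{MultiConformerModel}.
#' @export
stripAltlocs <- function(model, keep = NULL) {
  at <- model@atoms
  keyv <- residueKey(at)
  keep_rows <- rep(TRUE, nrow(at))
  for (key in unique(keyv[at$alt != ""])) {
    rows <- which(keyv == key)
    alts <- at$alt[rows]
    labs <- sort(unique(alts[alts != ""]))
    choose <- if (!is.null(keep) && keep %in% labs) keep else {
      occ <- vapply(labs, function(l) at$o[rows[alts == l]][1L], numeric(1))
      labs[order(-occ, labs)][1L]
    }
    keep_rows[rows[alts != "" & alts != choose]] <- FALSE
  }
  at <- at[keep_rows, , drop = FALSE]
  at$alt <- ""
  at$o <- 1
  MultiConformerModel(at, title = model@title)
}
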