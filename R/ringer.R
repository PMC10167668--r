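# Ringer-style circular density traces: rotate the probe atom of each chi
# dihedral through 360 degrees and interpolate the sigma-scaled map at its
# positions.  The sampled dihedral grid is absolute: sample angle theta IS
# the chi value, not an offset from the current conformation.

#' RingerTrace: circular density profile around one chi dihedral
#'
#' @slot chain,resno,insert,restype Residue identity.
#' @slot chiIndex Which chi was sampled.
#' @slot probeAtom Name of the atom whose center was interpolated (the first
#'   atom distal to the rotating bond, e.g. CG for chi1).
#' @slot step Sampling step in degrees.
#' @slot angles Sample angles, \code{seq(0, 360 - step, step)}.
#' @slot values Map density in sigma units at each sample angle.
#' @export
setClass("RingerTrace",
         representation(chain = "character", resno = "integer",
                        insert = "character", restype = "character",
                        chiIndex = "integer", probeAtom = "character",
                        step = "numeric", angles = "numeric",
                        values = "numeric"))

setValidity("RingerTrace", function(object) {
  msg <- character(0)
  n <- length(object@angles)
  if (n < 2L || length(object@values) != n)
    msg <- c(msg, "angles and values must have equal length >= 2")
  else {
    if (object@angles[1L] != 0 ||
        max(abs(diff(object@angles) - object@step)) > 1e-9)
      msg <- c(msg, "angles must start at 0 with even spacing = step")
    if (abs(360 / object@step - round(360 / object@step)) > 1e-9)
      msg <- c(msg, "step must divide 360")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
  }
  if (length(msg) == 0L) TRUE else msg
})

setMethod("show", "RingerTrace", function(object) {
  cat(sprintf("RingerTrace %s %s%d%s chi%d (probe %s), %d samples, max %.2f sigma at %g deg\n",
              object@restype, object@chain, object@resno, object@insert,
              object@chiIndex, object@probeAtom, length(object@angles),
              max(object@values), object@angles[which.max(object@values)]))
})

#' Sample map density around one chi dihedral
#'
#' Rigidly rotates the probe atom (the fourth atom of the chi quadruple)
#' about the chi bond axis so that the dihedral takes each sample angle in
#' turn, preserving its bond length and bond angle, and interpolates the
#' sigma-scaled map at each position.
#'
#' @param map A sigma-scaled \code{DensityMap}.
#' @param model A \code{MultiConformerModel}.
#' @param chain,resno,insert Residue to sample.
#' @param chiIndex Which chi dihedral.
#' @param step Sampling step in degrees (must divide 360; default 10).
#' @param alt Conformer to start from (default: "A" if present, else blank).
#' @return A \code{RingerTrace}.
#' @export
ringerTrace <- function(map, model, chain, resno, insert = "", chiIndex,
                        step = 10, alt = NULL) {
  if (!isSigmaScaled(map))
    stop("map must be sigma-scaled before Ringer sampling")
  if (abs(360 / step - round(360 / step)) > 1e-9)
    stop("step must divide 360")
  at <- model@atoms
  sel <- at$chain == chain & at$resno == resno & at$insert == insert
  if (!any(sel)) stop("residue ", chain, " ", resno, insert, " not found")
  restype <- at$resid[sel][1L]
  if (is.null(alt)) {
    alts <- residueAltlocs(model, chain, resno, insert)
    alt <- if (length(alts) > 0L) alts[1L] else ""
  }
  coords <- residueCoords(model, chain, resno, insert, alt = alt)
  defs <- chiDefinitions(restype)
  if (chiIndex < 1L || chiIndex > length(defs))
    stop("residue type ", restype, " has no chi", chiIndex)
  quad <- defs[[chiIndex]]$atomQuadruple
  missing <- setdiff(quad, rownames(coords))
  if (length(missing) > 0L)
    stop("incomplete side chain: ", restype, " ", chain, resno,
         " missing ", paste(missing, collapse = ", "))
  p <- coords[quad, , drop = FALSE]
  theta0 <- measureDihedral(p[1L, ], p[2L, ], p[3L, ], p[4L, ])
  angles <- seq(0, 360 - step, by = step)
  # +delta about the q2-to-q3 axis direction increases the dihedral
  positions <- t(vapply(angles, function(th) {
    rotateAboutAxis(p[4L, ], origin = p[3L, ], axis = p[3L, ] - p[2L, ],
                    deg = th - theta0)
  }, numeric(3)))
  values <- interpolateMap(map, positions)
  new("RingerTrace", chain = chain, resno = as.integer(resno),
      insert = insert, restype = restype, chiIndex = as.integer(chiIndex),
      probeAtom = quad[4L], step = step, angles = angles, values = values)
}

#' Sample every chi of every eligible residue
#'
#' Residues other than the rotameric standard amino acids (GLY, ALA and PRO
#' are excluded, as are HETATM records) are not sampled; residues with
#' incomplete side chains are skipped with a message.
#'
#' @inheritParams ringerTrace
#' @return A list of \code{RingerTrace} objects with a \code{"skipped"}
#'   attribute (data.frame of skipped residues and reasons).
#' @export
ringerTraces <- function(map, model, step = 10, alt = NULL) {
  res <- residueTable(model)
  res <- res[res$resid %in% names(.CHI_ATOMS), , drop = FALSE]
  traces <- list()
  skipped <- list()
  for (i in seq_len(nrow(res))) {
    n <- nChi(res$resid[i])
    for (k in seq_len(n)) {
      tr <- tryCatch(
        ringerTrace(map, model, res$chain[i], res$resno[i], res$insert[i],
                    chiIndex = k, step = step, alt = alt),
        error = function(e) e)
      if (inherits(tr, "error")) {
        message("skipping ", res$resid[i], " ", res$chain[i], res$resno[i],
                " chi", k, ": ", conditionMessage(tr))
        skipped[[length(skipped) + 1L]] <-
          data.frame(chain = res$chain[i], resno = res$resno[i],
                     insert = res$insert[i], restype = res$resid[i],
                     chi = k, reason = conditionMessage(tr))
      } else {
        traces[[length(traces) + 1L]] <- tr
      }
    }
  }
  attr(traces, "skipped") <- if (length(skipped) > 0L)
    do.call(rbind, skipped)
  else
    data.frame(chain = character(0), resno = integer(0),
               insert = character(0), restype = character(0),
               chi = integer(0), reason = character(0))
  traces
}

#' Flatten Ringer traces to a data.frame
#' @param traces List of \code{RingerTrace} objects.
#' @return data.frame: chain, resi, restype, chi, angle, sigma_density.
#' @export
tracesToDataFrame <- function(traces) {
  if (length(traces) == 0L)
    return(data.frame(chain = character(0), resi = integer(0),
                      restype = character(0), chi = integer(0),
                      angle = numeric(0), sigma_density = numeric(0)))
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(chain = tr@chain, resi = tr@resno, restype = tr@restype,
               chi = tr@chiIndex, angle = tr@angles,
               sigma_density = tr@values)
  }))
}
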