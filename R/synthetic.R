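# Synthetic ground-truth data: Gaussian-atom density rendering and a registry
# of multi-conformer fixtures with machine-readable truth tables.
#
# The forward model places one isotropic Gaussian per heavy atom with width
# from the atomic B factor via B = 8 pi^2 <u^2> and amplitude proportional to
# the element's electron count, weighted by occupancy.  This emulates the
# essential features of a 2mFo-DFc map (occupancy-weighted, B-smeared atomic
# density) without Fourier truncation ripple or solvent contributions; the
# rscc calculation uses the same forward model.

.ELEMENT_Z <- c(C = 6, N = 7, O = 8, S = 16)

# Gaussian width (variance, A^2) from an isotropic B factor.
bToVariance <- function(b) b / (8 * pi^2)

# Peak (raw) density of one atom of element `el` at occupancy `occ`.
gaussianPeakDensity <- function(el, b, occ = 1) {
  s2 <- bToVariance(b)
  occ * .ELEMENT_Z[[el]] / (2 * pi * s2)^1.5
}

# Density of a set of atoms evaluated at Cartesian points, with periodic
# wrapping in the given cell.  atoms: data.frame with x,y,z,o,b,elesy.
gaussianDensityAt <- function(atoms, xyz, cell) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  M <- orthoMatrix(cell)
  fracPts <- cartToFrac(xyz, cell)
  val <- numeric(nrow(xyz))
  for (i in seq_len(nrow(atoms))) {
    z <- .ELEMENT_Z[[atoms$elesy[i]]]
    s2 <- bToVariance(atoms$b[i])
    amp <- atoms$o[i] * z / (2 * pi * s2)^1.5
    fa <- cartToFrac(c(atoms$x[i], atoms$y[i], atoms$z[i]), cell)
    df <- sweep(fracPts, 2L, fa)
    df <- df - round(df)             # nearest periodic image
    d <- t(M %*% t(df))
    r2 <- rowSums(d * d)
    val <- val + amp * exp(-r2 / (2 * s2))
  }
  val
}

#' Render a Gaussian-atom density map
#'
#' Computes an occupancy-weighted Gaussian-atom density over a periodic P1
#' grid, optionally adding i.i.d. Gaussian noise, and returns it as an
#' unscaled \code{DensityMap}.  Atoms outside the cell are wrapped in with a
#' warning.
#'
#' @param model A \code{MultiConformerModel} (occupancies and B factors are
#'   used by the forward model).
#' @param cell Unit-cell parameters (default 20 angstrom cube).
#' @param spacing Target grid spacing in angstrom (default 0.25).
#' @param noiseSd Standard deviation of added Gaussian noise, in raw
#'   (pre-scaling) density units.
#' @param seed Integer seed fixing the noise (required when noiseSd > 0).
#' @return An unscaled \code{DensityMap}.
#' @export
renderMap <- function(model, cell = c(20, 20, 20, 90, 90, 90),
                      spacing = 0.25, noiseSd = 0, seed = NULL) {
  atoms <- model@atoms
  n <- as.integer(round(cell[1:3] / spacing))
  if (any(spacing >= cell[1:3] / 4))
    stop("grid spacing must be finer than a quarter of the cell")
  grid <- array(0, dim = n)
  M <- orthoMatrix(cell)
  fr <- cartToFrac(as.matrix(atoms[, c("x", "y", "z")]), cell)
  if (any(fr < 0 | fr >= 1))
    warning("atoms outside the unit cell were wrapped periodically")
  for (i in seq_len(nrow(atoms))) {
    z <- .ELEMENT_Z[[atoms$elesy[i]]]
    s2 <- bToVariance(atoms$b[i])
    amp <- atoms$o[i] * z / (2 * pi * s2)^1.5
    cutoff <- 4.5 * sqrt(s2)
    half <- ceiling(cutoff * n / cell[1:3]) + 1L
    ctr <- round(fr[i, ] * n)
    off <- expand.grid(x = -half[1L]:half[1L],
                       y = -half[2L]:half[2L],
                       z = -half[3L]:half[3L])
    nodes <- sweep(as.matrix(off), 2L, ctr, `+`)
    df <- sweep(sweep(nodes, 2L, n, `/`), 2L, fr[i, ])
    df <- df - round(df)
    d <- t(M %*% t(df))
    r2 <- rowSums(d * d)
    keep <- r2 <= cutoff^2
    idx <- cbind(nodes[keep, 1L] %% n[1L] + 1L,
                 nodes[keep, 2L] %% n[2L] + 1L,
                 nodes[keep, 3L] %% n[3L] + 1L)
    grid[idx] <- grid[idx] + amp * exp(-r2[keep] / (2 * s2))
  }
  if (noiseSd > 0) {
    if (is.null(seed)) stop("a seed is required when adding noise")
    set.seed(as.integer(seed))
    grid <- grid + array(stats::rnorm(prod(n), 0, noiseSd), dim = n)
  }
  DensityMap(grid, cell)
}

# One residue as an atom data.frame block.
residueAtomBlock <- function(xyz, restype, chain, resno, alt, occ, b) {
  data.frame(type = "ATOM", eleno = NA_integer_, elety = rownames(xyz),
             alt = alt, resid = restype, chain = chain, resno = resno,
             insert = "", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             o = occ, b = b, elesy = atomElement(rownames(xyz)),
             stringsAsFactors = FALSE)
}

# Fixture registry.  Each case: residues with true rotamer names and
# occupancies, CA centers, and a cell size.  The input model carries only
# the major conformer of every residue; the rendered map comes from the full
# truth model.
.FIXTURE_CASES <- list(
  single_conformer = list(
    cell = 20,
    residues = list(list(restype = "SER", rotamers = "m", occ = 1,
                         center = c(10, 10, 10)))),
  serine_70_30 = list(
    cell = 20,
    residues = list(list(restype = "SER", rotamers = c("m", "p"),
                         occ = c(0.7, 0.3), center = c(10, 10, 10)))),
  methionine_chi3_split = list(
    cell = 20,
    residues = list(list(restype = "MET", rotamers = c("mtp", "mtm"),
                         occ = c(0.5, 0.5), center = c(10, 10, 10)))),
  tyrosine_minor = list(
    cell = 24,
    residues = list(list(restype = "TYR", rotamers = c("t80", "m-85"),
                         occ = c(0.88, 0.12), center = c(12, 12, 12)))),
  lysine_chi3_split = list(
    cell = 24,
    residues = list(list(restype = "LYS", rotamers = c("mttt", "mtmt"),
                         occ = c(0.74, 0.26), center = c(12, 12, 12)))),
  loop_multi = list(
    cell = 28,
    residues = list(
      list(restype = "SER", rotamers = c("m", "p"), occ = c(0.5, 0.5),
           center = c(7, 7, 7), resno = 1),
      list(restype = "GLN", rotamers = c("mt-30", "mm-40"), occ = c(0.6, 0.4),
           center = c(19, 7, 8), resno = 2),
      list(restype = "MET", rotamers = c("mtp", "mtm"), occ = c(0.5, 0.5),
           center = c(7, 19, 9), resno = 3),
      list(restype = "THR", rotamers = c("m", "p"), occ = c(0.7, 0.3),
           center = c(19, 19, 10), resno = 4),
      list(restype = "SER", rotamers = c("m", "t"), occ = c(0.65, 0.35),
           center = c(13, 13, 19), resno = 5)))
)

#' Names of the bundled synthetic fixtures
#' @return Character vector of fixture case names.
#' @export
fixtureCases <- function() names(.FIXTURE_CASES)

#' Generate a ground-truth synthetic fixture
#'
#' Builds a known multi-conformer model, renders its Gaussian-atom density
#' map at the stated occupancy split, and returns (optionally writes) the
#' single-conformer input model, the map and a truth table.  The noise level
#' is expressed as a fraction of the weakest conformer's probe-atom peak
#' density, the quantity that limits detectability.
#'
#' @param case One of \code{fixtureCases()}.
#' @param seed Integer seed for the map noise.
#' @param dir Output directory; \code{NULL} returns objects without writing.
#' @param noiseLevel Noise standard deviation, expressed relative to
#'   \code{noiseRef} (default 0.1).
#' @param noiseRef What \code{noiseLevel} is a fraction of:
#'   \code{"mapSigma"} (default) scales it by the noise-free map's standard
#'   deviation, so the default gives roughly 0.1-sigma noise -- the quality
#'   regime of the high-resolution deposited maps these fixtures emulate;
#'   \code{"minorPeak"} scales it by the weakest conformer's probe-atom peak
#'   density, the detectability-limiting quantity used by the noise-sweep
#'   stress tests.
#' @param spacing Grid spacing (angstrom).
#' @param bIso Isotropic B factor given to every atom (angstrom^2).
#' @param library Rotamer library.
#' @return List with \code{inputModel}, \code{truthModel}
#'   (\code{MultiConformerModel}s), \code{map} (unscaled \code{DensityMap}),
#'   \code{truth} (data.frame: chain, resno, restype, rotamer, occupancy),
#'   \code{noiseSd} (the raw-unit sd actually applied), and file paths when
#'   \code{dir} is given.
#' @examples
#' fx <- makeFixture("serine_70_30", seed = 1)
#' fx$truth
#' @export
makeFixture <- function(case, seed = 1, dir = NULL, noiseLevel = 0.1,
                        noiseRef = c("mapSigma", "minorPeak"),
                        spacing = 0.25, bIso = 15,
                        library = loadRotamerLibrary()) {
  noiseRef <- match.arg(noiseRef)
  if (!case %in% names(.FIXTURE_CASES))
    stop("unknown fixture case '", case, "'; available: ",
         paste(names(.FIXTURE_CASES), collapse = ", "))
  cfg <- .FIXTURE_CASES[[case]]
  cell <- c(rep(cfg$cell, 3L), 90, 90, 90)
  truthRows <- list()
  inputRows <- list()
  truthTab <- list()
  minPeak <- Inf
  for (i in seq_along(cfg$residues)) {
    r <- cfg$residues[[i]]
    resno <- if (is.null(r$resno)) i else r$resno
    nconf <- length(r$rotamers)
    labels <- if (nconf == 1L) "" else LETTERS[seq_len(nconf)]
    for (j in seq_len(nconf)) {
      xyz <- buildIdealResidue(r$restype, r$rotamers[j], library,
                               center = r$center)
      truthRows[[length(truthRows) + 1L]] <-
        residueAtomBlock(xyz, r$restype, "A", resno, labels[j], r$occ[j], bIso)
      truthTab[[length(truthTab) + 1L]] <-
        data.frame(chain = "A", resno = resno, restype = r$restype,
                   rotamer = r$rotamers[j], occupancy = r$occ[j])
    }
    major <- which.max(r$occ)
    xyzM <- buildIdealResidue(r$restype, r$rotamers[major], library,
                              center = r$center)
    inputRows[[length(inputRows) + 1L]] <-
      residueAtomBlock(xyzM, r$restype, "A", resno, "", 1, bIso)
    # detectability floor: the weakest conformer's probe-atom peak density
    defs <- chiDefinitions(r$restype)
    splitChi <- 1L
    if (nconf > 1L) {
      e1 <- rotamersFor(library, r$restype)
      a <- lapply(r$rotamers, function(nm)
        modalAngles(e1[e1$rotamer_name == nm, , drop = FALSE]))
      for (k in seq_along(defs)) {
        angs <- vapply(a, function(x) x[k], numeric(1))
        if (max(circularDiff(angs, angs[1L])) > 5) { splitChi <- k; break }
      }
    }
    probe <- defs[[splitChi]]$atomQuadruple[4L]
    minPeak <- min(minPeak, gaussianPeakDensity(atomElement(probe), bIso,
                                                min(r$occ)))
  }
  truthModel <- MultiConformerModel(do.call(rbind, truthRows))
  inputModel <- MultiConformerModel(do.call(rbind, inputRows))
  truth <- do.call(rbind, truthTab)
  map <- renderMap(truthModel, cell = cell, spacing = spacing)
  ref <- if (noiseRef == "minorPeak") minPeak
         else sqrt(mean((map@grid - mean(map@grid))^2))
  noiseSd <- noiseLevel * ref
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    g <- map@grid + array(stats::rnorm(length(map@grid), 0, noiseSd),
                          dim = dim(map@grid))
    map <- DensityMap(g, cell)
  }
  out <- list(case = case, inputModel = inputModel, truthModel = truthModel,
              map = map, truth = truth, noiseSd = noiseSd, cell = cell)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$modelPath <- file.path(dir, paste0(case, "_input.pdb"))
    out$mapPath <- file.path(dir, paste0(case, ".ccp4"))
    out$truthPath <- file.path(dir, paste0(case, "_truth.csv"))
    writeModel(inputModel, out$modelPath)
    writeCCP4Map(map, out$mapPath)
    utils::write.csv(truth, out$truthPath, row.names = FALSE)
  }
  out
}
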