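# Real-space density maps: CCP4/MRC reading and writing, sigma scaling and
# periodic trilinear interpolation in fractional coordinates.
#
# The grid is stored with array dimension i running along crystal axis i
# (a, b, c), regardless of the axis order (MAPC/MAPR/MAPS) of the file it
# came from; that is the package's canonical order.  Only P1 periodicity is
# applied: maps are wrapped through the unit cell but never expanded by
# crystallographic symmetry.

#' @import methods
NULL

#' DensityMap: a sigma-scalable real-space map
#'
#' @slot grid 3-D numeric array; dimension i runs along unit-cell axis i.
#' @slot cell Unit-cell parameters \code{c(a, b, c, alpha, beta, gamma)}
#'   (angstrom / degrees).
#' @slot gridShape Integer full-cell sampling counts along a, b, c.
#' @slot originOffset Integer grid-index offset of the stored block
#'   (CCP4 NCSTART/NRSTART/NSSTART reordered to axis order).
#' @slot sigmaScaled Whether the grid is in sigma units (mean 0, sd 1).
#' @slot meanRaw,sdRaw The raw-map statistics used for sigma scaling
#'   (NA before scaling).
#' @export
setClass("DensityMap",
         representation(grid = "array", cell = "numeric",
                        gridShape = "integer", originOffset = "integer",
                        sigmaScaled = "logical", meanRaw = "numeric",
                        sdRaw = "numeric"))

setValidity("DensityMap", function(object) {
  msg <- character(0)
  if (length(dim(object@grid)) != 3L) msg <- c(msg, "grid must be 3-D")
  if (length(object@cell) != 6L || any(object@cell[1:3] <= 0))
    msg <- c(msg, "cell must be 6 values with positive lengths")
  if (any(object@gridShape <= 0L)) msg <- c(msg, "gridShape must be positive")
  if (isTRUE(object@sigmaScaled)) {
    m <- mean(object@grid)
    s <- stats::sd(as.numeric(object@grid)) * sqrt((length(object@grid) - 1) /
                                                   length(object@grid))
    if (abs(m) > 1e-6 || abs(s - 1) > 1e-6)
      msg <- c(msg, "sigma-scaled grid must have mean 0 and sd 1")
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Construct a DensityMap from a grid array
#' @param grid 3-D numeric array (dimension i along cell axis i).
#' @param cell Unit-cell parameters \code{c(a, b, c, alpha, beta, gamma)}.
#' @param originOffset Grid offset of the stored block (default 0,0,0).
#' @param gridShape Full-cell sampling (defaults to \code{dim(grid)}).
#' @return A \code{DensityMap} (not sigma-scaled).
#' @export
DensityMap <- function(grid, cell, originOffset = c(0L, 0L, 0L),
                       gridShape = dim(grid)) {
  new("DensityMap", grid = grid, cell = as.numeric(cell),
      gridShape = as.integer(gridShape),
      originOffset = as.integer(originOffset),
      sigmaScaled = FALSE, meanRaw = NA_real_, sdRaw = NA_real_)
}

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap %dx%dx%d grid, cell %.2f %.2f %.2f / %.1f %.1f %.1f%s\n",
              dim(object@grid)[1L], dim(object@grid)[2L], dim(object@grid)[3L],
              object@cell[1L], object@cell[2L], object@cell[3L],
              object@cell[4L], object@cell[5L], object@cell[6L],
              if (object@sigmaScaled) ", sigma-scaled" else ""))
})

#' @rdname mapAccessors
#' @param map A \code{DensityMap}.
#' @return \code{mapGrid}: the 3-D grid array; \code{mapCell}: the length-6
#'   cell vector; \code{isSigmaScaled}: logical.
#' @export
mapGrid <- function(map) map@grid

#' @rdname mapAccessors
#' @name mapAccessors
#' @title DensityMap accessors
#' @export
mapCell <- function(map) map@cell

#' @rdname mapAccessors
#' @export
isSigmaScaled <- function(map) map@sigmaScaled

# Orthogonalization matrix: columns express the a, b, c axes in a Cartesian
# frame (a along x, b in the xy plane).  cart = M %*% frac.
orthoMatrix <- function(cell) {
  a <- cell[1L]; b <- cell[2L]; c <- cell[3L]
  al <- cell[4L] * pi / 180; be <- cell[5L] * pi / 180; ga <- cell[6L] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, 0, 0,
           b * cos(ga), b * sin(ga), 0,
           c * cos(be), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           c * v / sin(ga)),
         nrow = 3L)
}

#' Convert fractional to Cartesian coordinates
#' @param frac n x 3 matrix (or length-3 vector) of fractional coordinates.
#' @param cell Unit-cell parameters.
#' @return Cartesian coordinates, same shape.
#' @export
fracToCart <- function(frac, cell) {
  M <- orthoMatrix(cell)
  if (is.null(dim(frac))) as.numeric(M %*% frac) else t(M %*% t(frac))
}

#' Convert Cartesian to fractional coordinates
#' @param xyz n x 3 matrix (or length-3 vector) of Cartesian coordinates.
#' @param cell Unit-cell parameters.
#' @return Fractional coordinates, same shape.
#' @export
cartToFrac <- function(xyz, cell) {
  Mi <- solve(orthoMatrix(cell))
  if (is.null(dim(xyz))) as.numeric(Mi %*% xyz) else t(Mi %*% t(xyz))
}

#' Read a CCP4/MRC map
#'
#' Reads a mode-2 (32-bit float) CCP4/MRC map, normalizing any axis order
#' (MAPC/MAPR/MAPS) to the canonical order in which array dimension i runs
#' along cell axis i.  Both byte orders are handled.
#'
#' @param path Map file.
#' @return An unscaled \code{DensityMap}.
#' @export
readCCP4Map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readHeader <- function(endian) {
    seek(con, 0L)
    h <- list()
    h$dims <- readBin(con, "integer", 3L, size = 4L, endian = endian)
    h$mode <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    h$start <- readBin(con, "integer", 3L, size = 4L, endian = endian)
    h$sampling <- readBin(con, "integer", 3L, size = 4L, endian = endian)
    h$cell <- readBin(con, "numeric", 6L, size = 4L, endian = endian)
    h$axes <- readBin(con, "integer", 3L, size = 4L, endian = endian)
    h$stats <- readBin(con, "numeric", 3L, size = 4L, endian = endian)
    h$ispg <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    h$nsymbt <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    h
  }
  endian <- "little"
  h <- readHeader(endian)
  plausible <- function(h) {
    !any(is.na(h$dims)) && all(h$dims > 0L) && all(h$dims < 1e7) &&
      h$mode %in% 0:6 && all(sort(h$axes) == 1:3)
  }
  if (!plausible(h)) {
    endian <- "big"
    h <- readHeader(endian)
    if (!plausible(h)) stop("not a readable CCP4/MRC map: ", path)
  }
  if (h$mode != 2L)
    stop("only mode-2 (float) CCP4/MRC maps are supported; got mode ", h$mode)
  if (any(!is.finite(h$cell[1:3])) || any(h$cell[1:3] <= 0))
    stop("map is missing unit-cell parameters; supply a map with a complete ",
         "cell description")
  seek(con, 1024L + h$nsymbt)
  nval <- prod(h$dims)
  vals <- readBin(con, "numeric", nval, size = 4L, endian = endian)
  if (length(vals) < nval) stop("truncated map file: ", path)
  arr <- array(vals, dim = h$dims)
  # permute so that dimension k runs along cell axis k
  perm <- match(1:3, h$axes)
  grid <- aperm(arr, perm)
  start <- h$start[perm]
  DensityMap(grid, h$cell, originOffset = start, gridShape = h$sampling)
}

#' Write a CCP4 map
#'
#' @param map A \code{DensityMap}.
#' @param path Output file.
#' @param axisOrder Permutation of 1:3 giving the cell axes stored as
#'   columns, rows, sections (MAPC, MAPR, MAPS).
#' @return \code{path}, invisibly.
#' @export
writeCCP4Map <- function(map, path, axisOrder = c(1L, 2L, 3L)) {
  stopifnot(all(sort(axisOrder) == 1:3))
  grid <- map@grid
  # our canonical order has axis k on dimension k; put axisOrder[1] fastest
  arr <- aperm(grid, axisOrder)
  start <- map@originOffset[axisOrder]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  g <- as.numeric(arr)
  wi(dim(arr))                         # NC NR NS
  wi(2L)                               # MODE
  wi(start)                            # NCSTART NRSTART NSSTART
  wi(map@gridShape)                    # NX NY NZ
  wf(map@cell)                         # cell
  wi(axisOrder)                        # MAPC MAPR MAPS
  wf(c(min(g), max(g), mean(g)))       # AMIN AMAX AMEAN
  wi(1L)                               # ISPG (P1)
  wi(0L)                               # NSYMBT
  wi(rep(0L, 28L))                     # EXTRA (words 25-52)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)  # word 53
  wi(16708L)                           # machine stamp (little-endian, 0x4144)
  wf(stats::sd(g))                     # RMS
  wi(0L)                               # NLABL
  writeBin(raw(800L), con)             # labels
  writeBin(g, con, size = 4L, endian = "little")
  invisible(path)
}

#' Sigma-scale a map
#'
#' Normalizes the grid to zero mean and unit standard deviation over all
#' stored grid points, the "sigma units" in which detection thresholds are
#' expressed.  The population standard deviation is used.
#'
#' @param map An unscaled \code{DensityMap}.
#' @return A sigma-scaled \code{DensityMap} with \code{meanRaw}/\code{sdRaw}
#'   recording the statistics that were applied.
#' @export
sigmaScale <- function(map) {
  if (map@sigmaScaled) stop("map is already sigma-scaled")
  g <- as.numeric(map@grid)
  m <- mean(g)
  s <- sqrt(mean((g - m)^2))
  if (s == 0) stop("flat map: zero variance, cannot sigma-scale")
  out <- map
  out@grid <- array((map@grid - m) / s, dim = dim(map@grid))
  out@sigmaScaled <- TRUE
  out@meanRaw <- m
  out@sdRaw <- s
  validObject(out)
  out
}

#' Interpolate map density at Cartesian positions
#'
#' Trilinear interpolation in fractional coordinates with periodic unit-cell
#' wrapping (P1).  Positions outside the cell are wrapped back in; values at
#' grid nodes are reproduced exactly.
#'
#' @param map A \code{DensityMap} covering the full unit cell.
#' @param xyz n x 3 matrix (or length-3 vector) of Cartesian positions.
#' @return Numeric vector of interpolated densities.
#' @export
interpolateMap <- function(map, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (any(!is.finite(xyz))) stop("non-finite interpolation position")
  if (!all(dim(map@grid) == map@gridShape))
    stop("periodic interpolation requires a map covering the full unit cell")
  frac <- cartToFrac(xyz, map@cell)
  n <- map@gridShape
  g <- map@grid
  # continuous grid index (0-based) relative to the stored origin
  tt <- sweep(sweep(frac, 2L, n, `*`), 2L, map@originOffset)
  i0 <- floor(tt)
  w <- tt - i0
  val <- numeric(nrow(xyz))
  for (corner in 0:7) {
    dx <- bitwAnd(corner, 1L)
    dy <- bitwAnd(bitwShiftR(corner, 1L), 1L)
    dz <- bitwAnd(bitwShiftR(corner, 2L), 1L)
    ix <- ((i0[, 1L] + dx) %% n[1L]) + 1L
    iy <- ((i0[, 2L] + dy) %% n[2L]) + 1L
    iz <- ((i0[, 3L] + dz) %% n[3L]) + 1L
    wt <- (if (dx) w[, 1L] else 1 - w[, 1L]) *
      (if (dy) w[, 2L] else 1 - w[, 2L]) *
      (if (dz) w[, 3L] else 1 - w[, 3L])
    val <- val + wt * g[cbind(ix, iy, iz)]
  }
  val
}
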