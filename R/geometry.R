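# Low-level vector geometry shared by the dihedral, building and sampling code.
# All angles are degrees; dihedrals follow the signed IUPAC convention and live
# in the half-open interval [-180, 180).

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by the chain p1-p2-p3-p4 using the
#' two-plane-normal construction, returned in degrees on the half-open
#' interval \code{[-180, 180)} with the IUPAC sign convention (looking from
#' p2 towards p3, a clockwise rotation of p4 relative to p1 is positive).
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian coordinates (angstrom).
#' @return Dihedral angle in degrees, in \code{[-180, 180)}.
#' @examples
#' measureDihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
#' @export
measureDihedral <- function(p1, p2, p3, p4) {
  stopifnot(all(is.finite(c(p1, p2, p3, p4))))
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap180(ang)
}

# Wrap an angle (deg) into [-180, 180)
wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  hi <- which(a >= 180)  # guards the exact boundary after fp %% noise
  a[hi] <- a[hi] - 360
  a
}

# Wrap an angle (deg) into [0, 360)
wrap360 <- function(a) a %% 360

# Smallest absolute circular difference between two angles (deg).
# period = 180 handles chemically symmetric terminal dihedrals.
circularDiff <- function(a, b, period = 360) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Rotate points (n x 3 matrix or length-3 vector) about the axis through
# `origin` with direction `axis` by `deg` degrees (right-hand rule).
rotateAboutAxis <- function(points, origin, axis, deg) {
  k <- vunit(axis)
  th <- deg * pi / 180
  onerow <- is.null(dim(points))
  p <- if (onerow) matrix(points, nrow = 1L) else points
  v <- sweep(p, 2L, origin)
  kv <- as.numeric(v %*% k)
  cr <- cbind(k[2L] * v[, 3L] - k[3L] * v[, 2L],
              k[3L] * v[, 1L] - k[1L] * v[, 3L],
              k[1L] * v[, 2L] - k[2L] * v[, 1L])
  vr <- v * cos(th) + cr * sin(th) + outer(kv * (1 - cos(th)), k)
  out <- sweep(vr, 2L, -origin)
  if (onerow) as.numeric(out) else out
}

# Place atom D relative to the chain A-B-C so that |D-C| = bond,
# angle(B,C,D) = angle and torsion(A,B,C,D) = torsion (NeRF construction).
placeAtom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  p <- vcross(n, bc)
  as.numeric(c + bond * (-cos(th) * bc + sin(th) * (cos(ph) * p + sin(ph) * n)))
}
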