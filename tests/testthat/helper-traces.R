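# Shared helpers: hand-built circular traces and tiny map constructors.

# A RingerTrace with the given values on a regular grid (step deg).
mkTrace <- function(values, step = 10, restype = "SER", chi = 1L) {
  new("RingerTrace", chain = "A", resno = 1L, insert = "",
      restype = restype, chiIndex = chi, probeAtom = "OG",
      step = step, angles = seq(0, 360 - step, by = step),
      values = values)
}

# A smooth circular bump of the given height centered at `center` degrees,
# with angular width sigma (deg), evaluated on the sampling grid.
circularBump <- function(center, height, sigmaDeg = 25, step = 10) {
  ang <- seq(0, 360 - step, by = step)
  d <- pmin(abs(ang - center), 360 - abs(ang - center))
  height * exp(-d^2 / (2 * sigmaDeg^2))
}

# An independent dihedral implementation for cross-checks: magnitude from
# the plane normals, sign from the scalar triple product.
oracleDihedral <- function(p1, p2, p3, p4) {
  n1 <- pracma::cross(p2 - p1, p3 - p2)
  n2 <- pracma::cross(p3 - p2, p4 - p3)
  co <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, co))) * 180 / pi
  s <- sign(sum(pracma::cross(n1, n2) * (p3 - p2)))
  out <- if (s < 0) -ang else ang
  if (out >= 180) out - 360 else out
}
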