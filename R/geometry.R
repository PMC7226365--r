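# Internal 3D geometry helpers shared by the builders and the dihedral code.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension (NeRF) placement: position atom D given positions of
# A, B, C so that |C-D| = bond, angle(B,C,D) = angle_deg and the torsion
# A-B-C-D equals torsion_deg (IUPAC sign convention).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180   # sign flip keeps IUPAC convention
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Signed torsion angle of four points
#'
#' IUPAC convention: looking down the p2->p3 bond, a clockwise rotation of
#' the far bond relative to the near bond is positive.  The result is
#' mapped to the half-open interval (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9) {
    stop("coincident points in dihedral")
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("collinear points in dihedral")
  }
  m1 <- cross3(n1, unitv(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# Map any angle in degrees to (-180, 180].
wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

# Minimal absolute circular distance between two angles (degrees).
circ_dist <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  d
}
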