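# Low-level vector geometry: dihedral measurement, analytic dihedral
# gradients, and internal-coordinate atom placement (NeRF).

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.norm3 <- function(v) sqrt(sum(v * v))

#' Measure a dihedral angle
#'
#' Returns the torsion angle defined by four points using the IUPAC sign
#' convention: 0 deg for the cis (eclipsed) arrangement, 180 deg for trans,
#' positive angles for clockwise rotation of `p4` relative to `p1` looking
#' down the `p2 -> p3` axis.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors, Angstrom.
#' @return Angle in degrees in (-180, 180].
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-10 || .norm3(n2) < 1e-10) {
    stop("collinear atoms: dihedral is undefined (degenerate cross product)")
  }
  u2 <- b2 / .norm3(b2)
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * u2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Analytic gradient of a dihedral angle
#'
#' Gradient of the dihedral (in radians) with respect to each of the four
#' defining positions, using the standard cross-product formulation. The
#' four gradients sum to zero (translation invariance) and have zero net
#' torque about the origin (rotation invariance).
#'
#' @inheritParams measure_dihedral
#' @return 4 x 3 matrix, radians per Angstrom; row k is d(angle)/d(p_k).
#' @export
dihedral_gradient <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  n1sq <- sum(n1 * n1)
  n2sq <- sum(n2 * n2)
  if (sqrt(n1sq) < 1e-10 || sqrt(n2sq) < 1e-10) {
    stop("collinear atoms: dihedral gradient is undefined")
  }
  nb2 <- .norm3(b2)
  g1 <- -(nb2 / n1sq) * n1
  g4 <- (nb2 / n2sq) * n2
  c12 <- sum(b1 * b2) / (nb2 * nb2)
  c32 <- sum(b3 * b2) / (nb2 * nb2)
  g2 <- -(1 + c12) * g1 + c32 * g4
  g3 <- c12 * g1 - (1 + c32) * g4
  rbind(g1, g2, g3, g4, deparse.level = 0)
}

# NeRF atom placement: position D bonded to C with bond length r,
# angle(B, C, D) = theta_deg and dihedral(A, B, C, D) = chi_deg.
.place_atom <- function(A, B, C, r, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180
  chi <- chi_deg * pi / 180
  bc <- C - B
  bc <- bc / .norm3(bc)
  ab <- B - A
  n <- .cross3(ab, bc)
  n <- n / .norm3(n)
  m <- .cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi), r * sin(theta) * sin(chi))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}
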