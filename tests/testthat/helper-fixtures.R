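# Shared fixtures and independent oracles, all built in code at test time.

# an n-residue alanine chain with random backbone dihedrals
random_conformation <- function(n = 5L) {
  build_ideal_peptide(strrep("A", n),
                      cbind(runif(n, -175, 175), runif(n, -175, 175)))
}

# rigid rotation (angle_deg about axis) plus translation of a structure
rigid_transform <- function(structure, angle_deg, axis, shift) {
  th <- angle_deg * pi / 180
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3L, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  structure$coordinates <- structure$coordinates %*% t(R) +
    matrix(shift, nrow(structure$coordinates), 3L, byrow = TRUE)
  structure
}

# independent dihedral oracle: acos magnitude + explicit sign test
dihedral_oracle <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# brute-force double-loop evaluation of a double Fourier series
surface_oracle <- function(coeffs, phi_deg, psi_deg) {
  p <- phi_deg * pi / 180; q <- psi_deg * pi / 180
  e <- 0
  for (m in 0:coeffs$max_order) for (n in 0:coeffs$max_order) {
    e <- e + coeffs$c_cc[m + 1, n + 1] * cos(m * p) * cos(n * q) +
      coeffs$c_cs[m + 1, n + 1] * cos(m * p) * sin(n * q) +
      coeffs$c_sc[m + 1, n + 1] * sin(m * p) * cos(n * q) +
      coeffs$c_ss[m + 1, n + 1] * sin(m * p) * sin(n * q)
  }
  e
}

# coefficient set for the separable single-minimum surface
# E = K [(1 - cos(phi - phi0)) + (1 - cos(psi - psi0))]
single_well_coeffs <- function(K, phi0_deg, psi0_deg) {
  co <- fourier_coefficients(1)
  p0 <- phi0_deg * pi / 180; q0 <- psi0_deg * pi / 180
  co$c_cc[1, 1] <- 2 * K
  co$c_cc[2, 1] <- -K * cos(p0)
  co$c_sc[2, 1] <- -K * sin(p0)
  co$c_cc[1, 2] <- -K * cos(q0)
  co$c_cs[1, 2] <- -K * sin(q0)
  co
}

# fast torsion energy of a structure (independent of torsion_forces):
# measure each residue's (phi, psi) and sum the vectorised surface
torsion_energy_oracle <- function(xyz, quad, coeffs) {
  ang <- vapply(seq_len(nrow(quad)), function(j) {
    measure_dihedral(xyz[quad$i1[j], ], xyz[quad$i2[j], ],
                     xyz[quad$i3[j], ], xyz[quad$i4[j], ])
  }, numeric(1))
  phis <- ang[quad$label == "phi"]
  psis <- ang[quad$label == "psi"]
  rp <- quad$residue_index[quad$label == "phi"]
  rs <- quad$residue_index[quad$label == "psi"]
  common <- intersect(rp, rs)
  sum(evaluate_surface(coeffs, phis[match(common, rp)],
                       psis[match(common, rs)]))
}

max_abs <- function(x) max(abs(x))
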