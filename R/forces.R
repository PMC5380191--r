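#' Torsion energy and analytic Cartesian forces
#'
#' Evaluates the coupled 2D torsion energy of a structure as the sum of
#' the surface over every residue with both a phi and a psi quadruplet,
#' and accumulates the analytic per-atom force
#' `F_k = -(dE/dphi dphi/dR_k + dE/dpsi dpsi/dR_k)` over all residues
#' touching atom k. Residues missing one of the two torsions (chain
#' termini) contribute nothing. The resulting force set has zero net force
#' and zero net torque.
#'
#' @param structure A [pepstructure()].
#' @param quadruplets Data frame from [enumerate_backbone_dihedrals()];
#'   computed from `structure` when omitted.
#' @param coeffs A [fourier_coefficients()].
#' @param exclude_proline Skip proline residues (their torsion term is
#'   conventionally left to the base force field).
#' @return List with `energy` (kcal/mol), `forces` (n_atoms x 3 matrix,
#'   kcal/mol/Angstrom) and `residues` (residue indices that contributed).
#' @export
torsion_forces <- function(structure, quadruplets = NULL, coeffs,
                           exclude_proline = FALSE) {
  if (is.null(quadruplets)) quadruplets <- enumerate_backbone_dihedrals(structure)
  xyz <- structure$coordinates
  forces <- matrix(0, nrow(xyz), 3L)
  energy <- 0
  used <- integer(0)
  res_with_phi <- quadruplets$residue_index[quadruplets$label == "phi"]
  res_with_psi <- quadruplets$residue_index[quadruplets$label == "psi"]
  complete <- intersect(res_with_phi, res_with_psi)
  if (exclude_proline) {
    rn <- vapply(complete, function(r) {
      structure$residue_names[match(r, structure$residue_indices)]
    }, character(1))
    complete <- complete[rn != "PRO"]
  }
  for (r in complete) {
    qp <- quadruplets[quadruplets$residue_index == r & quadruplets$label == "phi", ][1L, ]
    qs <- quadruplets[quadruplets$residue_index == r & quadruplets$label == "psi", ][1L, ]
    ip <- c(qp$i1, qp$i2, qp$i3, qp$i4)
    is <- c(qs$i1, qs$i2, qs$i3, qs$i4)
    phi <- measure_dihedral(xyz[ip[1L], ], xyz[ip[2L], ], xyz[ip[3L], ], xyz[ip[4L], ])
    psi <- measure_dihedral(xyz[is[1L], ], xyz[is[2L], ], xyz[is[3L], ], xyz[is[4L], ])
    energy <- energy + evaluate_surface(coeffs, phi, psi)
    d <- surface_partials(coeffs, phi, psi)
    gp <- dihedral_gradient(xyz[ip[1L], ], xyz[ip[2L], ], xyz[ip[3L], ], xyz[ip[4L], ])
    gs <- dihedral_gradient(xyz[is[1L], ], xyz[is[2L], ], xyz[is[3L], ], xyz[is[4L], ])
    forces[ip, ] <- forces[ip, ] - d$dphi * gp
    forces[is, ] <- forces[is, ] - d$dpsi * gs
    used <- c(used, r)
  }
  list(energy = energy, forces = forces, residues = used)
}

#' Export a force set as CSV
#'
#' Columns `atom_index,fx,fy,fz` (kcal/mol/Angstrom).
#'
#' @param forces n x 3 force matrix.
#' @param path CSV path.
#' @export
write_forces <- function(forces, path) {
  df <- data.frame(atom_index = seq_len(nrow(forces)),
                   fx = forces[, 1L], fy = forces[, 2L], fz = forces[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
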