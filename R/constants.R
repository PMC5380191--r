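#' Physical and geometric constants
#'
#' `kB_kcal` is the Boltzmann constant in kcal/(mol K). `backbone_geometry`
#' collects the fixed internal coordinates used by [build_ideal_peptide()]:
#' bond lengths in Angstrom, bond angles in degrees. The builder only
#' guarantees self-consistency (requested dihedrals are reproduced exactly);
#' the values are standard peptide geometry.
#'
#' @format `backbone_geometry` is a named list of numerics.
#' @name constants
NULL

#' @rdname constants
#' @export
kB_kcal <- 0.0019872041

#' @rdname constants
#' @export
backbone_geometry <- list(
  # bond lengths, Angstrom
  b_C_N  = 1.329,   # peptide C-N
  b_N_CA = 1.458,
  b_CA_C = 1.525,
  b_C_O  = 1.231,
  b_N_H  = 1.010,
  b_CA_HA = 1.090,
  b_CA_CB = 1.521,
  b_CB_IND = 2.400, # CB to tryptophan indole centroid pseudo-atom
  # bond angles, degrees
  a_CA_C_N = 116.6,
  a_C_N_CA = 121.7,
  a_N_CA_C = 111.2,
  a_CA_C_O = 120.8,
  a_C_N_H  = 119.5,
  a_C_C_O  = 121.1, # ACE methyl-C-O
  omega    = 180.0  # trans peptide bond
)

# 1-letter -> 3-letter residue codes accepted by the builder
.aa3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# approximate atomic masses for Rg weighting
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, X = 12.011)
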