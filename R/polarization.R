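#' Exponential polarization parameters
#'
#' Distance-dependent charge-transfer amplitudes for the backbone
#' hydrogen-bond polarization model `dq(d) = a * exp(-b * d)`, with
#' separate (a, b) for the amide nitrogen (N, paired with H) and the
#' carbonyl oxygen (O, paired with C). `d` is the donor-N to acceptor-O
#' distance; outside \[`d_min`, `d_max`\] the distance is clamped to the
#' fitted range. The shipped defaults are unofficial placeholders chosen
#' for a physically plausible magnitude (a few hundredths of an
#' elementary charge at hydrogen-bonding distances); fit your own with
#' [fit_exponential()].
#'
#' @param a_N,b_N Amplitude (e) and decay (1/Angstrom) for nitrogen.
#' @param a_O,b_O Amplitude (e) and decay (1/Angstrom) for oxygen.
#' @param d_min,d_max Validity range of the fit, Angstrom.
#' @return Object of class `polarization_params`.
#' @export
polarization_params <- function(a_N = 0.493, b_N = 1.0, a_O = -0.334,
                                b_O = 0.9, d_min = 2.5, d_max = 6.5) {
  if (b_N <= 0 || b_O <= 0) stop("decay constants must be positive")
  if (d_min >= d_max) stop("d_min must be below d_max")
  structure(list(a_N = a_N, b_N = b_N, a_O = a_O, b_O = b_O,
                 d_min = d_min, d_max = d_max),
            class = "polarization_params")
}

#' Charge alteration of a hydrogen-bonded atom
#'
#' `dq(d) = a * exp(-b * d)` with `d` clamped to the fitted range before
#' evaluation, so the model is flat beyond `d_max` (and below `d_min`).
#'
#' @param params A [polarization_params()].
#' @param d Donor-acceptor (N...O) distance, Angstrom; must be positive.
#' @param atom_kind `"N"` or `"O"`.
#' @return Charge delta in units of e (vectorised over `d`).
#' @export
delta_q <- function(params, d, atom_kind = c("N", "O")) {
  atom_kind <- match.arg(atom_kind)
  if (any(d <= 0)) stop("d must be positive")
  d <- pmin(pmax(d, params$d_min), params$d_max)
  if (atom_kind == "N") params$a_N * exp(-params$b_N * d)
  else params$a_O * exp(-params$b_O * d)
}

#' Fit the single-exponential charge model
#'
#' Nonlinear least squares for `dq = a * exp(-b * d)` with a log-linear
#' initial estimate refined by Levenberg-Marquardt. All `dq` samples must
#' share one sign (the model cannot change sign).
#'
#' @param d Distances, Angstrom (distinct, >= 3 samples).
#' @param dq Charge deltas, e.
#' @return Named numeric `c(a = , b = )`.
#' @export
fit_exponential <- function(d, dq) {
  if (length(d) < 3L || length(dq) != length(d))
    stop("need at least 3 (d, dq) samples of equal length")
  if (anyDuplicated(d)) stop("d values must be distinct")
  if (any(dq == 0) || length(unique(sign(dq))) != 1L)
    stop("dq samples must be nonzero and share one sign")
  sgn <- sign(dq[1L])
  lf <- stats::lm(log(abs(dq)) ~ d)
  a0 <- sgn * exp(unname(stats::coef(lf)[1L]))
  b0 <- -unname(stats::coef(lf)[2L])
  df <- data.frame(d = d, dq = dq)
  fit <- tryCatch(
    minpack.lm::nlsLM(dq ~ a * exp(-b * d), data = df,
                      start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  c(a = unname(p["a"]), b = unname(p["b"]))
}

#' Detect backbone hydrogen bonds
#'
#' Geometric criterion over all amide-donor / carbonyl-acceptor pairs:
#' N...O distance at most `d_cutoff`, N-H...O angle (at the hydrogen) at
#' least `angle_cutoff`, and donor and acceptor at least two residues
#' apart. Residues without an amide hydrogen are skipped (with a warning,
#' except prolines and chain-terminal residues that cannot carry one).
#'
#' @param structure A [pepstructure()].
#' @param d_cutoff Maximum N...O distance, Angstrom.
#' @param angle_cutoff Minimum N-H...O angle, degrees.
#' @return Data frame, sorted by donor residue then distance, with columns
#'   `donor_res`, `acceptor_res`, `n_idx`, `h_idx`, `o_idx`, `c_idx`,
#'   `d` (Angstrom) and `angle` (degrees).
#' @export
detect_hbonds <- function(structure, d_cutoff = 3.5, angle_cutoff = 120) {
  xyz <- structure$coordinates
  res_ids <- unique(structure$residue_indices)
  res_name <- vapply(res_ids, function(r) {
    structure$residue_names[match(r, structure$residue_indices)]
  }, character(1))
  first_res <- min(res_ids)
  donors <- list(); acceptors <- list()
  for (k in seq_along(res_ids)) {
    r <- res_ids[k]
    n_i <- .atom_index(structure, r, "N")
    h_i <- .atom_index(structure, r, "H")
    c_i <- .atom_index(structure, r, "C")
    o_i <- .atom_index(structure, r, "O")
    if (n_i > 0L) {
      if (h_i > 0L) {
        donors[[length(donors) + 1L]] <- c(r = r, n = n_i, h = h_i)
      } else if (!(res_name[k] %in% c("PRO", "NME")) && r != first_res) {
        warning(sprintf("residue %d has no amide H; skipped as donor", r))
      }
    }
    if (c_i > 0L && o_i > 0L)
      acceptors[[length(acceptors) + 1L]] <- c(r = r, c = c_i, o = o_i)
  }
  rows <- list()
  for (dn in donors) for (ac in acceptors) {
    if (abs(dn["r"] - ac["r"]) < 2) next
    d <- .norm3(xyz[dn["n"], ] - xyz[ac["o"], ])
    if (d > d_cutoff) next
    v1 <- xyz[dn["n"], ] - xyz[dn["h"], ]
    v2 <- xyz[ac["o"], ] - xyz[dn["h"], ]
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (.norm3(v1) * .norm3(v2))))) * 180 / pi
    if (ang < angle_cutoff) next
    rows[[length(rows) + 1L]] <- data.frame(
      donor_res = unname(dn["r"]), acceptor_res = unname(ac["r"]),
      n_idx = unname(dn["n"]), h_idx = unname(dn["h"]),
      o_idx = unname(ac["o"]), c_idx = unname(ac["c"]),
      d = d, angle = ang)
  }
  if (length(rows) == 0L)
    return(data.frame(donor_res = integer(0), acceptor_res = integer(0),
                      n_idx = integer(0), h_idx = integer(0),
                      o_idx = integer(0), c_idx = integer(0),
                      d = numeric(0), angle = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$donor_res, out$d), , drop = FALSE]
}

#' Per-atom charge set
#'
#' Base and polarized partial charges aligned with a structure's atom
#' order. Total charge is conserved by construction of the paired
#' transfers.
#'
#' @param base_charges Numeric vector, e, one per atom.
#' @param polarized_charges Numeric vector, e; defaults to base.
#' @param note Provenance note.
#' @return Object of class `charge_set`.
#' @export
charge_set <- function(base_charges, polarized_charges = base_charges,
                       note = "") {
  if (length(base_charges) != length(polarized_charges))
    stop("base and polarized charges must align")
  structure(list(base = base_charges, polarized = polarized_charges,
                 note = note), class = "charge_set")
}

# generic amide-group partial charges keyed by atom name
.default_q <- c(N = -0.4157, H = 0.2719, CA = 0.0337, HA = 0.0823,
                CB = -0.1825, C = 0.5973, O = -0.5679,
                CH3 = -0.1490, IND = 0.0)

#' Generic backbone charge set for a structure
#'
#' Assigns standard amide-group partial charges by atom name. Intended as
#' a convenient base set for exercising the polarization model, not as a
#' parameterized force field.
#'
#' @param structure A [pepstructure()].
#' @return A [charge_set()].
#' @export
backbone_charge_set <- function(structure) {
  q <- unname(.default_q[structure$atom_names])
  q[is.na(q)] <- 0
  charge_set(q, note = "generic amide charges by atom name")
}

#' Apply hydrogen-bond polarization to a charge set
#'
#' For each retained hydrogen bond the transfers are
#' `q_N += dq_N(d)`, `q_H -= dq_N(d)`, `q_O += dq_O(d)`, `q_C -= dq_O(d)`,
#' which conserves total charge exactly. When an atom appears in several
#' detected bonds only its shortest-distance bond is retained (the model
#' was parameterized on a single hydrogen-bonded pair); a bond is applied
#' only if it is the shortest for all four of its atoms.
#'
#' @param structure A [pepstructure()].
#' @param base A [charge_set()]; its `base` charges are the starting point.
#' @param params A [polarization_params()].
#' @param hbonds Data frame from [detect_hbonds()].
#' @return A [charge_set()] with updated `polarized` charges.
#' @export
apply_polarization <- function(structure, base, params, hbonds) {
  q <- base$base
  if (nrow(hbonds) > 0L) {
    atoms_of <- function(j) c(hbonds$n_idx[j], hbonds$h_idx[j],
                              hbonds$o_idx[j], hbonds$c_idx[j])
    keep <- vapply(seq_len(nrow(hbonds)), function(j) {
      all(vapply(atoms_of(j), function(a) {
        involved <- which(hbonds$n_idx == a | hbonds$h_idx == a |
                          hbonds$o_idx == a | hbonds$c_idx == a)
        j == involved[which.min(hbonds$d[involved])]
      }, logical(1)))
    }, logical(1))
    hb <- hbonds[keep, , drop = FALSE]
    touched <- integer(0)
    for (j in seq_len(nrow(hb))) {
      a4 <- c(hb$n_idx[j], hb$h_idx[j], hb$o_idx[j], hb$c_idx[j])
      if (any(a4 %in% touched))
        stop("internal error: atom polarized by two hydrogen bonds")
      touched <- c(touched, a4)
      dn <- delta_q(params, hb$d[j], "N")
      do <- delta_q(params, hb$d[j], "O")
      q[hb$n_idx[j]] <- q[hb$n_idx[j]] + dn
      q[hb$h_idx[j]] <- q[hb$h_idx[j]] - dn
      q[hb$o_idx[j]] <- q[hb$o_idx[j]] + do
      q[hb$c_idx[j]] <- q[hb$c_idx[j]] - do
    }
  }
  charge_set(base$base, q, note = "polarized")
}

#' Export a charge table as CSV
#'
#' Columns `atom_index,atom_name,base_q,polarized_q`.
#'
#' @param structure A [pepstructure()].
#' @param charges A [charge_set()].
#' @param path CSV path.
#' @export
write_charges <- function(structure, charges, path) {
  df <- data.frame(atom_index = seq_len(n_atoms(structure)),
                   atom_name = structure$atom_names,
                   base_q = charges$base, polarized_q = charges$polarized)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
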