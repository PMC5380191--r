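#' Peptide structure container
#'
#' A `pepstructure` holds one conformation: parallel per-atom vectors of
#' atom names (PDB convention), 3-letter residue names, 1-based residue
#' indices, element symbols, and an n x 3 coordinate matrix in Angstrom.
#'
#' @param atom_names Character vector of PDB atom names.
#' @param residue_names Character vector of 3-letter residue codes.
#' @param residue_indices Integer vector, 1-based, non-decreasing.
#' @param elements Character vector of element symbols.
#' @param coordinates Numeric n x 3 matrix, Angstrom.
#' @return An object of class `pepstructure`.
#' @export
pepstructure <- function(atom_names, residue_names, residue_indices,
                         elements, coordinates) {
  coordinates <- as.matrix(coordinates)
  n <- length(atom_names)
  if (nrow(coordinates) != n || ncol(coordinates) != 3L)
    stop("coordinate matrix must be n_atoms x 3")
  if (length(residue_names) != n || length(residue_indices) != n ||
      length(elements) != n)
    stop("per-atom vectors must all have the same length")
  if (!all(is.finite(coordinates)))
    stop("non-finite coordinates")
  if (is.unsorted(residue_indices))
    stop("residue_indices must be non-decreasing")
  structure(list(
    atom_names = as.character(atom_names),
    residue_names = as.character(residue_names),
    residue_indices = as.integer(residue_indices),
    elements = as.character(elements),
    coordinates = unname(coordinates)
  ), class = "pepstructure")
}

#' @export
print.pepstructure <- function(x, ...) {
  cat(sprintf("pepstructure: %d atoms, %d residues (%s)\n",
              n_atoms(x), length(unique(x$residue_indices)),
              paste(unique(x$residue_names), collapse = " ")))
  invisible(x)
}

#' @rdname pepstructure
#' @param x A `pepstructure`.
#' @export
n_atoms <- function(x) length(x$atom_names)

# index of a named atom within a residue; 0 if absent
.atom_index <- function(struct, residue_index, atom_name) {
  i <- which(struct$residue_indices == residue_index &
             struct$atom_names == atom_name)
  if (length(i) == 0L) 0L else i[1L]
}

#' Trajectory of conformations
#'
#' Ordered frames sharing one topology, with optional per-frame temperature
#' (K) and potential energy (kcal/mol) metadata.
#'
#' @param frames List of [pepstructure()] objects with identical atom count
#'   and ordering.
#' @param temperature Optional numeric vector, one value per frame, K.
#' @param energy Optional numeric vector, one value per frame, kcal/mol.
#' @return An object of class `peptrajectory`.
#' @export
peptrajectory <- function(frames, temperature = NULL, energy = NULL) {
  if (length(frames) == 0L) stop("trajectory needs at least one frame")
  na <- n_atoms(frames[[1L]])
  nm <- frames[[1L]]$atom_names
  for (i in seq_along(frames)) {
    if (n_atoms(frames[[i]]) != na || !identical(frames[[i]]$atom_names, nm))
      stop(sprintf("frame %d does not share the topology of frame 1", i))
  }
  for (meta in list(temperature, energy)) {
    if (!is.null(meta) && length(meta) != length(frames))
      stop("per-frame metadata length must match frame count")
  }
  structure(list(frames = frames, temperature = temperature, energy = energy),
            class = "peptrajectory")
}

#' @export
print.peptrajectory <- function(x, ...) {
  cat(sprintf("peptrajectory: %d frames x %d atoms\n",
              length(x$frames), n_atoms(x$frames[[1L]])))
  invisible(x)
}

#' Build an ideal peptide from internal coordinates
#'
#' Deterministic internal-coordinate (NeRF) construction of a peptide chain
#' with the requested backbone dihedrals and standard geometry (see
#' [backbone_geometry]). The peptide bond omega is fixed at 180 degrees.
#' Atoms placed per residue: N, CA, C, O, amide H (not on the first residue
#' of an uncapped chain), HA, CB (except glycine), and for tryptophan an
#' indole-centroid pseudo-atom named `IND` used for stacking distances.
#' `capped = TRUE` adds ACE/NME caps so that the first phi and last psi are
#' realised too.
#'
#' For an uncapped chain phi of residue 1 and psi of the last residue have
#' no defining atoms; those entries of `dihedrals` are ignored.
#'
#' @param sequence Character scalar of 1-letter residue codes (or a
#'   character vector of codes).
#' @param dihedrals Either a length-2 numeric vector `c(phi, psi)` applied
#'   to every residue, or an n x 2 matrix / list of pairs, degrees in
#'   \[-180, 180\].
#' @param capped Add ACE and NME capping groups.
#' @return A [pepstructure()].
#' @examples
#' helix <- build_ideal_peptide("AAAAA", c(-57, -47))
#' @export
build_ideal_peptide <- function(sequence, dihedrals, capped = FALSE) {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1L]]
  nres <- length(sequence)
  if (nres == 0L) stop("empty sequence")
  bad <- setdiff(sequence, names(.aa3))
  if (length(bad) > 0L)
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  res3 <- unname(.aa3[sequence])

  if (is.list(dihedrals)) dihedrals <- do.call(rbind, dihedrals)
  if (is.null(dim(dihedrals))) {
    if (length(dihedrals) != 2L)
      stop("dihedrals must be c(phi, psi) or one pair per residue")
    dihedrals <- matrix(rep(dihedrals, each = nres), nres, 2L)
  }
  dihedrals <- as.matrix(dihedrals)
  if (nrow(dihedrals) != nres)
    stop("need exactly one (phi, psi) pair per residue")
  if (any(abs(dihedrals) > 180))
    stop("dihedral angles must lie in [-180, 180] degrees")
  phi <- dihedrals[, 1L]
  psi <- dihedrals[, 2L]

  g <- backbone_geometry
  # Backbone pass over the extended atom sequence
  # [CH3, C]_ace, (N, CA, C) x nres, [N, CH3]_nme.
  # Placement torsions cycle psi(i) -> omega -> phi(i+1).
  bb <- list()   # each: list(name, pos)
  seed_len <- function(k) switch(k, `1` = 0, `2` = g$b_N_CA, g$b_CA_C)

  place_seq <- function(kinds, lens, angs, tors) {
    pos <- vector("list", length(kinds))
    pos[[1L]] <- c(0, 0, 0)
    pos[[2L]] <- c(lens[2L], 0, 0)
    a3 <- angs[3L] * pi / 180
    pos[[3L]] <- pos[[2L]] + lens[3L] * c(-cos(a3), sin(a3), 0)
    if (length(kinds) > 3L) {
      for (k in 4L:length(kinds)) {
        pos[[k]] <- .place_atom(pos[[k - 3L]], pos[[k - 2L]], pos[[k - 1L]],
                                lens[k], angs[k], tors[k])
      }
    }
    pos
  }

  # assemble the backbone atom plan
  kinds <- character(0); lens <- numeric(0); angs <- numeric(0)
  tors <- numeric(0); owner <- integer(0)
  add <- function(kind, len, ang, tor, own) {
    kinds <<- c(kinds, kind); lens <<- c(lens, len); angs <<- c(angs, ang)
    tors <<- c(tors, tor); owner <<- c(owner, own)
  }
  if (capped) {
    add("CH3", 0, 0, 0, 0L)
    add("C", g$b_CA_C, 0, 0, 0L)
  }
  for (i in seq_len(nres)) {
    # N placed with torsion psi(i-1); CA with omega; C with phi(i)
    add("N", g$b_C_N, g$a_CA_C_N, if (i > 1L) psi[i - 1L] else 0, i)
    add("CA", g$b_N_CA, g$a_C_N_CA, g$omega, i)
    add("C", g$b_CA_C, g$a_N_CA_C, phi[i], i)
  }
  if (capped) {
    add("N", g$b_C_N, g$a_CA_C_N, psi[nres], nres + 1L)
    add("CH3", g$b_N_CA, g$a_C_N_CA, g$omega, nres + 1L)
  }
  pos <- place_seq(kinds, lens, angs, tors)
  bbpos <- function(own, kind) {
    k <- which(owner == own & kinds == kind)
    if (length(k) == 0L) NULL else pos[[k[1L]]]
  }

  # decorate: O, H, HA, CB, IND per residue plus cap atoms
  a_nm <- character(0); r_nm <- character(0); r_ix <- integer(0)
  el <- character(0); xyz <- NULL
  emit <- function(name, resname, resix, elem, p) {
    a_nm <<- c(a_nm, name); r_nm <<- c(r_nm, resname)
    r_ix <<- c(r_ix, resix); el <<- c(el, elem)
    xyz <<- rbind(xyz, p)
  }

  res_offset <- if (capped) 1L else 0L
  if (capped) {
    ch3 <- bbpos(0L, "CH3"); cc <- bbpos(0L, "C"); n1 <- bbpos(1L, "N")
    o <- .place_atom(n1, ch3, cc, g$b_C_O, g$a_C_C_O, 180)
    emit("CH3", "ACE", 1L, "C", ch3)
    emit("C", "ACE", 1L, "C", cc)
    emit("O", "ACE", 1L, "O", o)
  }
  for (i in seq_len(nres)) {
    N <- bbpos(i, "N"); CA <- bbpos(i, "CA"); C <- bbpos(i, "C")
    prevC <- if (i > 1L) bbpos(i - 1L, "C") else if (capped) bbpos(0L, "C") else NULL
    prevCA <- if (i > 1L) bbpos(i - 1L, "CA") else if (capped) bbpos(0L, "CH3") else NULL
    nextN <- if (i < nres) bbpos(i + 1L, "N") else if (capped) bbpos(nres + 1L, "N") else NULL
    rix <- i + res_offset
    emit("N", res3[i], rix, "N", N)
    emit("CA", res3[i], rix, "C", CA)
    emit("C", res3[i], rix, "C", C)
    # carbonyl O anti to the next N about the CA-C axis
    psi_eff <- psi[i]
    emit("O", res3[i], rix, "O",
         .place_atom(N, CA, C, g$b_C_O, g$a_CA_C_O, psi_eff + 180))
    if (!is.null(prevC) && res3[i] != "PRO") {
      emit("H", res3[i], rix, "H",
           .place_atom(prevCA, prevC, N, g$b_N_H, g$a_C_N_H, 0))
    }
    # HA and CB from the local tetrahedral frame at CA
    u1 <- (N - CA) / .norm3(N - CA)
    u2 <- (C - CA) / .norm3(C - CA)
    bis <- -(u1 + u2); bis <- bis / .norm3(bis)
    prp <- .cross3(u1, u2); prp <- prp / .norm3(prp)
    half <- 54.75 * pi / 180
    d_cb <- cos(half) * bis + sin(half) * prp   # L-configuration side
    d_ha <- cos(half) * bis - sin(half) * prp
    emit("HA", res3[i], rix, "H", CA + g$b_CA_HA * d_ha)
    if (res3[i] != "GLY") {
      CB <- CA + g$b_CA_CB * d_cb
      emit("CB", res3[i], rix, "C", CB)
      if (res3[i] == "TRP") {
        emit("IND", res3[i], rix, "C",
             CB + g$b_CB_IND * (CB - CA) / .norm3(CB - CA))
      }
    }
  }
  if (capped) {
    nn <- bbpos(nres + 1L, "N"); nch3 <- bbpos(nres + 1L, "CH3")
    lastCA <- bbpos(nres, "CA"); lastC <- bbpos(nres, "C")
    rix <- nres + 2L
    emit("N", "NME", rix, "N", nn)
    emit("H", "NME", rix, "H",
         .place_atom(lastCA, lastC, nn, g$b_N_H, g$a_C_N_H, 0))
    emit("CH3", "NME", rix, "C", nch3)
  }
  pepstructure(a_nm, r_nm, r_ix, el, xyz)
}

#' Enumerate backbone dihedral quadruplets
#'
#' Lists the phi (C(i-1)-N(i)-CA(i)-C(i)) and psi (N(i)-CA(i)-C(i)-N(i+1))
#' quadruplets of a structure. For an n-residue uncapped chain this yields
#' n-1 phi and n-1 psi entries; ACE/NME caps contribute their C and N atoms
#' so that capped chains include the terminal-residue torsions.
#'
#' @param structure A [pepstructure()].
#' @return Data frame with columns `label` ("phi"/"psi"), `residue_index`,
#'   and 1-based atom indices `i1..i4`.
#' @export
enumerate_backbone_dihedrals <- function(structure) {
  res_ids <- unique(structure$residue_indices)
  res_name <- vapply(res_ids, function(r) {
    structure$residue_names[match(r, structure$residue_indices)]
  }, character(1))
  std <- !(res_name %in% c("ACE", "NME"))
  if (sum(std) < 2L && !any(res_name %in% c("ACE", "NME")))
    stop("need at least two residues with full backbone")

  need <- function(r, nm) {
    i <- .atom_index(structure, r, nm)
    if (i == 0L)
      stop(sprintf("residue %d is missing backbone atom %s", r, nm))
    i
  }
  rows <- list()
  for (k in which(std)) {
    r <- res_ids[k]
    prev <- if (k > 1L) res_ids[k - 1L] else NA_integer_
    nxt <- if (k < length(res_ids)) res_ids[k + 1L] else NA_integer_
    n_i <- need(r, "N"); ca_i <- need(r, "CA"); c_i <- need(r, "C")
    if (!is.na(prev)) {
      cp <- .atom_index(structure, prev, "C")
      if (cp == 0L && res_name[k - 1L] %in% c("ACE"))
        stop(sprintf("residue %d is missing backbone atom C", prev))
      if (cp > 0L)
        rows[[length(rows) + 1L]] <-
          data.frame(label = "phi", residue_index = r,
                     i1 = cp, i2 = n_i, i3 = ca_i, i4 = c_i)
    }
    if (!is.na(nxt)) {
      nn <- .atom_index(structure, nxt, "N")
      if (nn > 0L)
        rows[[length(rows) + 1L]] <-
          data.frame(label = "psi", residue_index = r,
                     i1 = n_i, i2 = ca_i, i3 = c_i, i4 = nn)
    }
  }
  do.call(rbind, rows)
}

#' Measure the backbone dihedrals of a structure
#'
#' Convenience wrapper: enumerates backbone quadruplets and measures each.
#'
#' @param structure A [pepstructure()].
#' @return Data frame with `label`, `residue_index`, `angle_deg`.
#' @export
measure_backbone_dihedrals <- function(structure) {
  q <- enumerate_backbone_dihedrals(structure)
  xyz <- structure$coordinates
  q$angle_deg <- vapply(seq_len(nrow(q)), function(j) {
    measure_dihedral(xyz[q$i1[j], ], xyz[q$i2[j], ],
                     xyz[q$i3[j], ], xyz[q$i4[j], ])
  }, numeric(1))
  q
}
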