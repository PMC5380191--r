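# Trajectory observables: RMSD, Rg, clustering, reaction coordinates,
# Ramachandran populations and J couplings.

# resolve an atom selection to indices
.select_atoms <- function(structure, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  if (length(selection) == 1L && selection %in% c("all", "backbone", "CA")) {
    return(switch(selection,
      all = seq_len(n_atoms(structure)),
      backbone = which(structure$atom_names %in% c("N", "CA", "C", "O")),
      CA = which(structure$atom_names == "CA")))
  }
  which(structure$atom_names %in% selection)
}

# optimal rotation (Kabsch, proper rotation enforced) mapping centred B
# onto centred A; returns list(R, center_a, center_b)
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  s <- svd(crossprod(B0, A0))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, center_a = ca, center_b = cb)
}

#' Minimal RMSD after optimal superposition
#'
#' Kabsch superposition (closed-form optimal rigid rotation plus
#' translation, proper rotation enforced) of the mobile selection onto
#' the reference selection, then root-mean-square deviation.
#'
#' @param mobile,reference [pepstructure()] objects (or n x 3 coordinate
#'   matrices) whose selections align 1:1.
#' @param atom_selection `"all"`, `"backbone"`, `"CA"`, atom names, or
#'   indices (applied to both structures).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(mobile, reference, atom_selection = "CA") {
  get_xyz <- function(s) {
    if (inherits(s, "pepstructure"))
      s$coordinates[.select_atoms(s, atom_selection), , drop = FALSE]
    else as.matrix(s)
  }
  A <- get_xyz(reference); B <- get_xyz(mobile)
  if (nrow(A) != nrow(B)) stop("selections do not align 1:1")
  if (nrow(A) < 3L) stop("need at least 3 atoms for superposition")
  k <- .kabsch(A, B)
  B_fit <- sweep(sweep(B, 2L, k$center_b) %*% t(k$R), 2L, k$center_a, `+`)
  sqrt(mean(rowSums((B_fit - A)^2)))
}

#' Radius of gyration
#'
#' `sqrt(sum w_i |r_i - r_cm|^2 / sum w_i)`, optionally mass-weighted by
#' element.
#'
#' @param structure A [pepstructure()].
#' @param atom_selection As in [kabsch_rmsd()].
#' @param mass_weighted Weight by atomic mass instead of uniformly.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(structure, atom_selection = "all",
                               mass_weighted = FALSE) {
  idx <- .select_atoms(structure, atom_selection)
  if (length(idx) == 0L) stop("empty atom selection")
  xyz <- structure$coordinates[idx, , drop = FALSE]
  w <- if (mass_weighted) {
    m <- .atomic_mass[structure$elements[idx]]
    m[is.na(m)] <- 12.011
    m
  } else rep(1, length(idx))
  cm <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2L, cm)^2)) / sum(w))
}

#' K-means conformational clustering of a trajectory
#'
#' Frames are featurized as the flattened coordinates of the selection
#' after superposition onto the first frame, then clustered with
#' [stats::kmeans()] (Lloyd iterations, multiple seeded starts). The
#' centroid frame of each cluster is the member closest to the cluster
#' mean. Deterministic under a fixed seed.
#'
#' @param trajectory A [peptrajectory()].
#' @param k Number of clusters (1 <= k <= n_frames).
#' @param atom_selection As in [kabsch_rmsd()].
#' @param seed Integer RNG seed.
#' @return List with `labels` (per frame), `centroid_frames` (frame index
#'   per cluster), `populations` (fractions summing to 1) and `inertia`
#'   (total within-cluster sum of squares).
#' @export
kmeans_cluster <- function(trajectory, k, atom_selection = "CA", seed) {
  frames <- trajectory$frames
  n <- length(frames)
  if (k < 1L || k > n) stop("k must lie in [1, n_frames]")
  if (missing(seed)) stop("an explicit seed is required")
  ref <- frames[[1L]]
  idx <- .select_atoms(ref, atom_selection)
  A <- ref$coordinates[idx, , drop = FALSE]
  ca <- colMeans(A)
  feats <- t(vapply(frames, function(fr) {
    B <- fr$coordinates[idx, , drop = FALSE]
    kk <- .kabsch(A, B)
    as.vector(sweep(sweep(B, 2L, kk$center_b) %*% t(kk$R), 2L, ca, `+`))
  }, numeric(3L * length(idx))))
  set.seed(seed)
  if (k == 1L) {
    centers <- matrix(colMeans(feats), 1L)
    labels <- rep(1L, n)
    inertia <- sum(sweep(feats, 2L, centers[1L, ])^2)
  } else {
    km <- stats::kmeans(feats, centers = k, nstart = 10L, iter.max = 100L)
    labels <- km$cluster
    centers <- km$centers
    inertia <- km$tot.withinss
  }
  centroid_frames <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    d2 <- rowSums(sweep(feats[members, , drop = FALSE], 2L, centers[cl, ])^2)
    members[which.min(d2)]
  }, integer(1))
  populations <- tabulate(labels, nbins = k) / n
  list(labels = labels, centroid_frames = centroid_frames,
       populations = populations, inertia = inertia)
}

#' Native-contact specification for hairpin reaction coordinates
#'
#' Defines the native inter-strand hydrogen bonds (donor residue,
#' acceptor residue pairs) behind the collective hydrogen-bond distance
#' `d`, and the tryptophan pairs behind the stacking distance `l`.
#'
#' @param hbond_pairs Two-column matrix/data frame of (donor residue,
#'   acceptor residue).
#' @param stacking_pairs Two-column matrix/data frame of TRP residue
#'   pairs. The default for a 12-residue tryptophan zipper pairs residues
#'   2-11 and 4-11; override to taste.
#' @return Object of class `native_contact_spec`.
#' @export
native_contact_spec <- function(hbond_pairs,
                                stacking_pairs = rbind(c(2, 11), c(4, 11))) {
  hbond_pairs <- as.matrix(hbond_pairs)
  stacking_pairs <- as.matrix(stacking_pairs)
  if (nrow(hbond_pairs) == 0L) stop("hbond_pairs must be non-empty")
  structure(list(hbond_pairs = hbond_pairs, stacking_pairs = stacking_pairs),
            class = "native_contact_spec")
}

#' Collective hydrogen-bond distance d
#'
#' Aggregates the N(donor)...O(acceptor) distances of the listed native
#' hydrogen-bond pairs; the default aggregation is the arithmetic mean
#' (`"max"` and `"rms"` are available).
#'
#' @param frame A [pepstructure()].
#' @param spec A [native_contact_spec()].
#' @param method Aggregation method.
#' @return d in Angstrom.
#' @export
collective_hbond_distance <- function(frame, spec,
                                      method = c("mean", "max", "rms")) {
  method <- match.arg(method)
  xyz <- frame$coordinates
  ds <- vapply(seq_len(nrow(spec$hbond_pairs)), function(j) {
    dr <- spec$hbond_pairs[j, 1L]; ar <- spec$hbond_pairs[j, 2L]
    ni <- .atom_index(frame, dr, "N"); oi <- .atom_index(frame, ar, "O")
    if (ni == 0L || oi == 0L)
      stop(sprintf("missing backbone atom for native pair %d -> %d", dr, ar))
    .norm3(xyz[ni, ] - xyz[oi, ])
  }, numeric(1))
  switch(method, mean = mean(ds), max = max(ds), rms = sqrt(mean(ds^2)))
}

# indole centroid of a TRP residue: pseudo-atom IND if present, else the
# mean of the indole ring heavy atoms
.indole_centroid <- function(frame, res) {
  rn <- frame$residue_names[match(res, frame$residue_indices)]
  if (is.na(rn) || rn != "TRP")
    stop(sprintf("residue %d is not TRP", res))
  i <- .atom_index(frame, res, "IND")
  if (i > 0L) return(frame$coordinates[i, ])
  ring <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  idx <- which(frame$residue_indices == res & frame$atom_names %in% ring)
  if (length(idx) == 0L)
    stop(sprintf("TRP %d has neither IND pseudo-atom nor indole ring atoms", res))
  colMeans(frame$coordinates[idx, , drop = FALSE])
}

#' Tryptophan stacking distance l
#'
#' Mean of the indole-centroid to indole-centroid distances over the
#' spec's stacking pairs.
#'
#' @inheritParams collective_hbond_distance
#' @return l in Angstrom.
#' @export
stacking_distance <- function(frame, spec) {
  ds <- vapply(seq_len(nrow(spec$stacking_pairs)), function(j) {
    a <- .indole_centroid(frame, spec$stacking_pairs[j, 1L])
    b <- .indole_centroid(frame, spec$stacking_pairs[j, 2L])
    .norm3(a - b)
  }, numeric(1))
  mean(ds)
}

#' Ramachandran region classifier
#'
#' An ordered list of labelled rectangle sets in (phi, psi) degrees;
#' classification takes the first region containing the point, with
#' `"other"` as the fallback, so every point maps to exactly one label.
#' The default boundaries are configurable stand-ins for the customary
#' alpha / PPII / beta boxes: alpha phi in \[-100, -30\], psi in
#' \[-67, -7\]; PPII phi in \[-110, -50\], psi in \[120, 180\]; beta phi
#' in \[-180, -90\], psi in \[90, 180\] or \[-180, -150\]. Setting
#' `strict_alpha = TRUE` replaces the alpha box by a tightened one
#' (phi in \[-80, -48\], psi in \[-59, -27\]).
#'
#' @param regions Optional named list: each element a list of
#'   `c(phi_min, phi_max, psi_min, psi_max)` rectangles; order is the
#'   match priority.
#' @param strict_alpha Use the tightened alpha definition.
#' @return Object of class `rama_classifier`.
#' @export
rama_classifier <- function(regions = NULL, strict_alpha = FALSE) {
  if (is.null(regions)) {
    alpha <- if (strict_alpha) list(c(-80, -48, -59, -27))
             else list(c(-100, -30, -67, -7))
    regions <- list(
      alpha = alpha,
      ppii = list(c(-110, -50, 120, 180)),
      beta = list(c(-180, -90, 90, 180), c(-180, -90, -180, -150))
    )
  }
  for (rg in regions) for (r in rg) {
    if (length(r) != 4L || any(r[c(1, 3)] > r[c(2, 4)]) ||
        any(abs(r) > 180))
      stop("each region rectangle must be c(phi_min, phi_max, psi_min, psi_max) within [-180, 180]")
  }
  structure(list(regions = regions), class = "rama_classifier")
}

#' Classify (phi, psi) samples into secondary-structure populations
#'
#' @param phi,psi Angles in degrees (vectors of equal length).
#' @param classifier A [rama_classifier()].
#' @return Named numeric of per-label fractions (including `other`),
#'   summing to 1 exactly.
#' @export
classify_conformations <- function(phi, psi, classifier = rama_classifier()) {
  stopifnot(length(phi) == length(psi))
  labels <- c(names(classifier$regions), "other")
  lab <- rep("other", length(phi))
  unassigned <- rep(TRUE, length(phi))
  for (nm in names(classifier$regions)) {
    hit <- rep(FALSE, length(phi))
    for (r in classifier$regions[[nm]]) {
      hit <- hit | (phi >= r[1L] & phi <= r[2L] & psi >= r[3L] & psi <= r[4L])
    }
    take <- unassigned & hit
    lab[take] <- nm
    unassigned <- unassigned & !take
  }
  counts <- table(factor(lab, levels = labels))
  out <- as.numeric(counts) / length(phi)
  names(out) <- labels
  out
}

#' Karplus parameters for 3J(HN,HA)
#'
#' `J(phi) = A cos^2(theta) + B cos(theta) + C` with
#' `theta = phi - phase`. The shipped defaults (A = 7.09, B = -1.42,
#' C = 1.55 Hz, phase 60 degrees) are the commonly used HN-HA
#' coefficients; treat them as replaceable configuration, not as an
#' official parameter set.
#'
#' @param A,B,C Karplus coefficients, Hz.
#' @param phase_deg Phase offset between phi and the H-N-CA-HA dihedral.
#' @return Object of class `karplus_params`.
#' @export
karplus_params <- function(A = 7.09, B = -1.42, C = 1.55, phase_deg = 60) {
  structure(list(A = A, B = B, C = C, phase_deg = phase_deg),
            class = "karplus_params")
}

#' Karplus 3J(HN,HA) coupling
#'
#' @param phi Backbone phi angle(s), degrees.
#' @param params A [karplus_params()].
#' @return J in Hz (vectorised). The ensemble average over frames is
#'   `mean(karplus_j(phi))`.
#' @export
karplus_j <- function(phi, params = karplus_params()) {
  th <- (phi - params$phase_deg) * pi / 180
  params$A * cos(th)^2 + params$B * cos(th) + params$C
}

#' Per-frame observable table for a trajectory
#'
#' Computes, for each frame: RMSD to a reference, radius of gyration,
#' optional reaction coordinates d and l (when a
#' [native_contact_spec()] is supplied), the majority Ramachandran label
#' over residues, and the residue-averaged Karplus J.
#'
#' @param trajectory A [peptrajectory()].
#' @param reference A [pepstructure()].
#' @param atom_selection Selection for RMSD/Rg.
#' @param spec Optional [native_contact_spec()].
#' @param classifier A [rama_classifier()].
#' @param karplus A [karplus_params()].
#' @return Data frame with columns `frame,rmsd,rg,d,l,label,J`.
#' @export
analyze_trajectory <- function(trajectory, reference,
                               atom_selection = "CA", spec = NULL,
                               classifier = rama_classifier(),
                               karplus = karplus_params()) {
  frames <- trajectory$frames
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    ang <- measure_backbone_dihedrals(fr)
    phis <- ang$angle_deg[ang$label == "phi"]
    psis <- ang$angle_deg[ang$label == "psi"]
    common <- intersect(ang$residue_index[ang$label == "phi"],
                        ang$residue_index[ang$label == "psi"])
    pp <- vapply(common, function(r) c(
      ang$angle_deg[ang$label == "phi" & ang$residue_index == r][1L],
      ang$angle_deg[ang$label == "psi" & ang$residue_index == r][1L]),
      numeric(2))
    fr_label <- if (length(common) > 0L) {
      fracs <- classify_conformations(pp[1L, ], pp[2L, ], classifier)
      names(fracs)[which.max(fracs)]
    } else "other"
    data.frame(
      frame = i,
      rmsd = kabsch_rmsd(fr, reference, atom_selection),
      rg = radius_of_gyration(fr, atom_selection),
      d = if (!is.null(spec)) collective_hbond_distance(fr, spec) else NA_real_,
      l = if (!is.null(spec) && nrow(spec$stacking_pairs) > 0L)
        stacking_distance(fr, spec) else NA_real_,
      label = fr_label,
      J = if (length(phis) > 0L) mean(karplus_j(phis, karplus)) else NA_real_)
  })
  do.call(rbind, rows)
}
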