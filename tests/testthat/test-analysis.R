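# RMSD, Rg, clustering, reaction coordinates, Ramachandran populations
# and Karplus couplings.

test_that("Kabsch RMSD is zero for identical and rigidly moved structures", {
  set.seed(61)
  s <- random_conformation(6)
  expect_lt(kabsch_rmsd(s, s, "all"), 1e-12)
  moved <- rigid_transform(s, 37, rnorm(3), c(5, -2, 9))
  expect_lt(kabsch_rmsd(moved, s, "all"), 1e-10)
})

test_that("fitted RMSD is minimal and symmetric", {
  set.seed(62)
  a <- random_conformation(6)
  b <- random_conformation(6)
  raw <- sqrt(mean(rowSums((a$coordinates - b$coordinates)^2)))
  fitted <- kabsch_rmsd(b, a, "all")
  expect_lte(fitted, raw + 1e-12)
  expect_lt(abs(kabsch_rmsd(a, b, "all") - kabsch_rmsd(b, a, "all")), 1e-10)
  expect_error(kabsch_rmsd(a, random_conformation(5), "all"), "align")
})

test_that("RMSD agrees with an independent superposition implementation", {
  set.seed(63)
  a <- random_conformation(5)
  b <- random_conformation(5)
  mine <- kabsch_rmsd(b, a, "CA")
  ca <- which(a$atom_names == "CA")
  ref <- bio3d::rmsd(as.vector(t(a$coordinates[ca, ])),
                     as.vector(t(b$coordinates[ca, ])),
                     fit = TRUE)
  expect_lt(abs(mine - ref), 1e-3)  # bio3d rounds to 3 decimals
})

test_that("radius of gyration matches hand-computable cases and a brute force", {
  one <- pepstructure("CA", "ALA", 1L, "C", matrix(c(1, 2, 3), 1))
  expect_equal(radius_of_gyration(one), 0)
  pair <- pepstructure(c("A1", "A2"), c("ALA", "ALA"), c(1L, 1L), c("C", "C"),
                       rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(pair), 1)
  set.seed(64)
  xyz <- matrix(rnorm(150), 50)
  cloud <- pepstructure(paste0("X", 1:50), rep("ALA", 50), rep(1L, 50),
                        rep("C", 50), xyz)
  cm <- colMeans(xyz)
  acc <- 0
  for (i in 1:50) acc <- acc + sum((xyz[i, ] - cm)^2)
  expect_lt(abs(radius_of_gyration(cloud) - sqrt(acc / 50)), 1e-12)
  expect_error(radius_of_gyration(cloud, integer(0)), "empty")
})

test_that("k-means separates a two-clump trajectory perfectly", {
  set.seed(65)
  helix <- build_ideal_peptide("AAAAAA", c(-57, -47))
  ext <- build_ideal_peptide("AAAAAA", c(180, 180))
  jitter_copies <- function(s, n) lapply(1:n, function(i) {
    s$coordinates <- s$coordinates +
      matrix(rnorm(length(s$coordinates), 0, 0.1), ncol = 3)
    s
  })
  tr <- peptrajectory(c(jitter_copies(helix, 12), jitter_copies(ext, 12)))
  cl <- kmeans_cluster(tr, 2, "CA", seed = 8)
  expect_equal(sort(cl$populations), c(0.5, 0.5))
  expect_equal(length(unique(cl$labels[1:12])), 1)
  expect_equal(length(unique(cl$labels[13:24])), 1)
  expect_false(cl$labels[1] == cl$labels[24])
  expect_equal(sum(cl$populations), 1)
  # centroid frames belong to their cluster
  expect_equal(cl$labels[cl$centroid_frames], 1:2)
})

test_that("k-means degenerate cases behave", {
  s <- build_ideal_peptide("AAAA", c(-57, -47))
  tr <- peptrajectory(list(s, s, s))
  one <- kmeans_cluster(tr, 1, "CA", seed = 3)
  expect_equal(one$populations, 1)
  expect_equal(one$inertia, 0)
  expect_error(kmeans_cluster(tr, 5, "CA", seed = 3), "k must lie")
})

test_that("reaction coordinates d and l aggregate native-pair distances", {
  w <- build_ideal_peptide("SWTWENGKWTWK", c(-120, 130))
  spec <- native_contact_spec(rbind(c(3, 10), c(5, 8)),
                              rbind(c(2, 11), c(4, 9)))
  d <- collective_hbond_distance(w, spec)
  xyz <- w$coordinates
  at <- function(r, nm) which(w$residue_indices == r & w$atom_names == nm)
  d1 <- sqrt(sum((xyz[at(3, "N"), ] - xyz[at(10, "O"), ])^2))
  d2 <- sqrt(sum((xyz[at(5, "N"), ] - xyz[at(8, "O"), ])^2))
  expect_equal(d, (d1 + d2) / 2)
  expect_equal(collective_hbond_distance(w, spec, method = "max"), max(d1, d2))
  expect_equal(collective_hbond_distance(w, spec, method = "rms"),
               sqrt((d1^2 + d2^2) / 2))
  # l is the mean of the indole centroid distances
  l <- stacking_distance(w, spec)
  c1 <- xyz[at(2, "IND"), ]; c2 <- xyz[at(11, "IND"), ]
  c3 <- xyz[at(4, "IND"), ]; c4 <- xyz[at(9, "IND"), ]
  expect_equal(l, (sqrt(sum((c1 - c2)^2)) + sqrt(sum((c3 - c4)^2))) / 2)
  # rigid-motion invariance of both internal coordinates
  moved <- rigid_transform(w, 71, c(0, 1, 1), c(-3, 8, 2))
  expect_lt(abs(collective_hbond_distance(moved, spec) - d), 1e-10)
  expect_lt(abs(stacking_distance(moved, spec) - l), 1e-10)
  # compact helix has smaller d than the extended chain under the same spec
  ext <- build_ideal_peptide("SWTWENGKWTWK", c(180, 180))
  hel <- build_ideal_peptide("SWTWENGKWTWK", c(-57, -47))
  expect_lt(collective_hbond_distance(hel, spec),
            collective_hbond_distance(ext, spec))
  expect_lt(stacking_distance(hel, spec), stacking_distance(ext, spec))
  # errors: non-TRP stacking residue, missing backbone pair
  bad <- native_contact_spec(rbind(c(3, 10)), rbind(c(1, 11)))
  expect_error(stacking_distance(w, bad), "not TRP")
  far <- native_contact_spec(rbind(c(3, 40)))
  expect_error(collective_hbond_distance(w, far), "pair 3 -> 40")
})

test_that("Ramachandran classification partitions samples exactly", {
  expect_equal(unname(classify_conformations(-57, -47)["alpha"]), 1)
  set.seed(66)
  phi <- runif(500, -180, 180); psi <- runif(500, -180, 180)
  fr <- classify_conformations(phi, psi)
  expect_identical(sum(fr), 1)
  expect_named(fr, c("alpha", "ppii", "beta", "other"))
  # empty region list: everything is "other"
  empty <- rama_classifier(regions = structure(list(), names = character(0)))
  fr0 <- classify_conformations(phi, psi, empty)
  expect_equal(unname(fr0["other"]), 1)
  # first-match priority: a point in the ppii/beta overlap goes to ppii
  fr1 <- classify_conformations(-100, 150)
  expect_equal(unname(fr1["ppii"]), 1)
  # strict alpha excludes the loose-box margin
  strict <- rama_classifier(strict_alpha = TRUE)
  expect_equal(unname(classify_conformations(-95, -60, strict)["other"]), 1)
  expect_equal(unname(classify_conformations(-60, -45, strict)["alpha"]), 1)
})

test_that("Karplus couplings follow the three-parameter cosine form", {
  kp <- karplus_params(A = 7.09, B = -1.42, C = 1.55, phase_deg = 60)
  expect_equal(karplus_j(60, kp), 7.09 - 1.42 + 1.55)
  expect_equal(karplus_j(150, kp), 1.55)
  expect_equal(mean(karplus_j(c(60, 150), kp)),
               (7.09 - 1.42 + 2 * 1.55) / 2)
})

test_that("MC sampling of a deep alpha well gives alpha populations and the quadrature J", {
  # K = 20 kcal/mol makes the thermal spread (~10 deg) sit well inside the
  # default alpha box: box occupancy by quadrature is 0.974
  co <- single_well_coeffs(20, -57, -47)
  cfg <- mc_config(temperature_K = 300, n_steps = 1e5, step_size_deg = 40,
                   seed = 67)
  ch <- metropolis_mc(co, cfg)
  fr <- classify_conformations(ch$phi, ch$psi)
  expect_gt(fr["alpha"], 0.9)
  # quadrature oracle for the Boltzmann-averaged J over the phi marginal
  beta <- 1 / (kB_kcal * 300)
  wfun <- function(x) exp(-beta * 20 * (1 - cos(x - (-57 * pi / 180))))
  Z <- stats::integrate(wfun, -pi, pi)$value
  Jbar <- stats::integrate(function(x) karplus_j(x * 180 / pi) * wfun(x),
                           -pi, pi)$value / Z
  expect_lt(abs(mean(karplus_j(ch$phi)) - Jbar), 0.1)
})

test_that("trajectory analysis tables carry the expected observables", {
  helix <- build_ideal_peptide("AAAAAA", c(-57, -47))
  ext <- build_ideal_peptide("AAAAAA", c(180, 180))
  tr <- peptrajectory(list(helix, ext))
  obs <- analyze_trajectory(tr, helix)
  expect_equal(names(obs), c("frame", "rmsd", "rg", "d", "l", "label", "J"))
  expect_lt(obs$rmsd[1], 1e-10)
  expect_gt(obs$rmsd[2], 1)
  expect_equal(obs$label, c("alpha", "other"))
  expect_true(all(is.finite(obs$J)))
})
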