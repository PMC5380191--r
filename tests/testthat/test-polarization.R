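# Hydrogen-bond detection and the exponential charge-transfer model.

test_that("an ideal alpha-helix donates exclusively to residue i-4", {
  h <- build_ideal_peptide(strrep("A", 12), c(-57, -47))
  hb <- detect_hbonds(h, d_cutoff = 3.5, angle_cutoff = 120)
  expect_gt(nrow(hb), 0)
  expect_true(all(hb$donor_res - hb$acceptor_res == 4))
  # brute-force oracle over every donor/acceptor pair
  xyz <- h$coordinates
  brute <- 0
  for (dr in unique(h$residue_indices)) for (ar in unique(h$residue_indices)) {
    if (abs(dr - ar) < 2) next
    ni <- which(h$residue_indices == dr & h$atom_names == "N")
    hi <- which(h$residue_indices == dr & h$atom_names == "H")
    oi <- which(h$residue_indices == ar & h$atom_names == "O")
    if (!length(ni) || !length(hi) || !length(oi)) next
    d <- sqrt(sum((xyz[ni, ] - xyz[oi, ])^2))
    v1 <- xyz[ni, ] - xyz[hi, ]; v2 <- xyz[oi, ] - xyz[hi, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (d <= 3.5 && ang >= 120) brute <- brute + 1
  }
  expect_equal(nrow(hb), brute)
})

test_that("extended chains and degenerate cutoffs yield no hydrogen bonds", {
  e <- build_ideal_peptide(strrep("A", 10), c(180, 180))
  expect_equal(nrow(detect_hbonds(e)), 0)
  h <- build_ideal_peptide(strrep("A", 10), c(-57, -47))
  expect_equal(nrow(detect_hbonds(h, d_cutoff = 0)), 0)
})

test_that("delta_q follows the clamped exponential form", {
  p <- polarization_params(a_N = 0.5, b_N = 1.0, a_O = -0.2, b_O = 1.5)
  expect_equal(delta_q(p, 2.5, "N"), 0.5 * exp(-2.5))
  expect_equal(delta_q(p, 3.0, "O"), -0.2 * exp(-1.5 * 3.0))
  # clamping outside the fitted range
  expect_equal(delta_q(p, 10, "N"), delta_q(p, 6.5, "N"))
  expect_equal(delta_q(p, 0.3, "N"), delta_q(p, 2.5, "N"))
  expect_error(delta_q(p, -1, "N"), "positive")
  pz <- polarization_params(a_N = 0)
  expect_equal(delta_q(pz, 3.3, "N"), 0)
  # |dq| decreases monotonically across the valid range
  d <- seq(2.5, 6.5, length.out = 40)
  expect_true(all(diff(abs(delta_q(p, d, "N"))) < 0))
  expect_true(all(diff(abs(delta_q(p, d, "O"))) < 0))
})

test_that("exponential fitting recovers generating parameters", {
  d <- seq(2.5, 6.5, length.out = 17)
  f <- fit_exponential(d, 0.31 * exp(-0.92 * d))
  expect_lt(abs(f["a"] - 0.31) / 0.31, 1e-6)
  expect_lt(abs(f["b"] - 0.92) / 0.92, 1e-6)
  # negative amplitude, same-sign samples
  fn <- fit_exponential(d, -0.2 * exp(-1.5 * d))
  expect_lt(abs(fn["a"] + 0.2) / 0.2, 1e-6)
  expect_lt(abs(fn["b"] - 1.5) / 1.5, 1e-6)
  # property: recovery over 50 random parameter draws
  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, 0.05, 1) * sample(c(-1, 1), 1)
    b <- runif(1, 0.3, 2)
    fr <- fit_exponential(d, a * exp(-b * d))
    expect_lt(abs(fr["a"] - a) / abs(a), 1e-6)
    expect_lt(abs(fr["b"] - b) / b, 1e-6)
  }
})

test_that("noisy samples are recovered to 1e-2 relative error", {
  set.seed(32)
  d <- seq(2.5, 6.5, length.out = 17)
  dq <- 0.31 * exp(-0.92 * d) + rnorm(17, 0, 1e-4)
  f <- fit_exponential(d, dq)
  expect_lt(abs(f["a"] - 0.31) / 0.31, 1e-2)
  expect_lt(abs(f["b"] - 0.92) / 0.92, 1e-2)
})

test_that("fitting rejects invalid sample sets", {
  d <- seq(2.5, 6.5, length.out = 9)
  expect_error(fit_exponential(d[1:2], c(1, 2)), "3")
  expect_error(fit_exponential(d, c(rep(0.1, 8), -0.1)), "sign")
  expect_error(fit_exponential(c(d[-1], d[2]), rep(0.1, 9)), "distinct")
})

test_that("polarization transfers conserve total charge exactly", {
  h <- build_ideal_peptide(strrep("A", 12), c(-57, -47))
  base <- backbone_charge_set(h)
  params <- polarization_params(a_N = 0.3, b_N = 1, a_O = -0.2, b_O = 1)
  hb <- detect_hbonds(h)
  pol <- apply_polarization(h, base, params, hb)
  expect_lt(abs(sum(pol$polarized) - sum(pol$base)), 1e-12)
  # only the N, H, C, O atoms of detected bonds change
  changed <- which(pol$polarized != pol$base)
  allowed <- unique(unlist(hb[, c("n_idx", "h_idx", "o_idx", "c_idx")]))
  expect_true(all(changed %in% allowed))
  # empty bond list is the identity
  none <- apply_polarization(h, base, params,
                             detect_hbonds(h, d_cutoff = 0))
  expect_identical(none$polarized, base$base)
})

test_that("a single hydrogen bond moves charge by the hand-computed delta", {
  h <- build_ideal_peptide(strrep("A", 6), c(-57, -47))
  base <- backbone_charge_set(h)
  params <- polarization_params(a_N = 0.3, b_N = 1, a_O = -0.2, b_O = 1)
  hb <- data.frame(donor_res = 5, acceptor_res = 1,
                   n_idx = which(h$residue_indices == 5 & h$atom_names == "N"),
                   h_idx = which(h$residue_indices == 5 & h$atom_names == "H"),
                   o_idx = which(h$residue_indices == 1 & h$atom_names == "O"),
                   c_idx = which(h$residue_indices == 1 & h$atom_names == "C"),
                   d = 3.0, angle = 160)
  pol <- apply_polarization(h, base, params, hb)
  expect_equal(pol$polarized[hb$n_idx] - base$base[hb$n_idx], 0.3 * exp(-3))
  expect_equal(pol$polarized[hb$h_idx] - base$base[hb$h_idx], -0.3 * exp(-3))
  expect_equal(pol$polarized[hb$o_idx] - base$base[hb$o_idx], -0.2 * exp(-3))
  expect_equal(pol$polarized[hb$c_idx] - base$base[hb$c_idx], 0.2 * exp(-3))
  expect_lt(abs(sum(pol$polarized) - sum(base$base)), 1e-12)
})

test_that("atoms in several bonds are polarized by the shortest partner only", {
  h <- build_ideal_peptide(strrep("A", 8), c(-57, -47))
  base <- backbone_charge_set(h)
  params <- polarization_params(a_N = 0.3, b_N = 1, a_O = -0.2, b_O = 1)
  at <- function(r, nm) which(h$residue_indices == r & h$atom_names == nm)
  # one O accepting from two donors at different distances
  hb <- data.frame(donor_res = c(5, 6), acceptor_res = c(1, 1),
                   n_idx = c(at(5, "N"), at(6, "N")),
                   h_idx = c(at(5, "H"), at(6, "H")),
                   o_idx = c(at(1, "O"), at(1, "O")),
                   c_idx = c(at(1, "C"), at(1, "C")),
                   d = c(3.2, 2.9), angle = c(150, 150))
  pol <- apply_polarization(h, base, params, hb)
  # only the shorter (d = 2.9) bond acts
  expect_equal(pol$polarized[at(6, "N")] - base$base[at(6, "N")],
               0.3 * exp(-2.9))
  expect_identical(pol$polarized[at(5, "N")], base$base[at(5, "N")])
  expect_lt(abs(sum(pol$polarized) - sum(base$base)), 1e-12)
})

test_that("charge conservation holds for arbitrary random bond sets", {
  set.seed(33)
  h <- build_ideal_peptide(strrep("A", 10), c(-57, -47))
  base <- backbone_charge_set(h)
  at <- function(r, nm) which(h$residue_indices == r & h$atom_names == nm)
  for (rep in 1:20) {
    params <- polarization_params(a_N = runif(1, -1, 1), b_N = runif(1, 0.2, 2),
                                  a_O = runif(1, -1, 1), b_O = runif(1, 0.2, 2))
    donors <- sample(3:10, 4)
    acceptors <- sample(1:8, 4)
    ok <- abs(donors - acceptors) >= 2
    if (!any(ok)) next
    hb <- data.frame(donor_res = donors[ok], acceptor_res = acceptors[ok],
                     n_idx = sapply(donors[ok], at, "N"),
                     h_idx = sapply(donors[ok], at, "H"),
                     o_idx = sapply(acceptors[ok], at, "O"),
                     c_idx = sapply(acceptors[ok], at, "C"),
                     d = runif(sum(ok), 2.6, 6.4), angle = 150)
    pol <- apply_polarization(h, base, params, hb)
    expect_lt(abs(sum(pol$polarized) - sum(base$base)), 1e-12)
  }
})
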