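#' Multi-temperature WHAM over a replica ensemble
#'
#' Binned temperature-WHAM self-consistent iteration over the density of
#' states: with per-replica histograms `n_i(b)` over shared energy bins,
#' `Omega(b) = sum_i n_i(b) / sum_i N_i exp(f_i - beta_i E_b)` and
#' `exp(-f_i) = sum_b Omega(b) exp(-beta_i E_b)`, iterated until
#' `max |delta f| <= tolerance`. `f` is normalised so `f_1 = 0`.
#' Deterministic given its inputs.
#'
#' @param ensemble A [replica_ensemble()].
#' @param n_energy_bins Number of energy bins spanning the pooled sample
#'   range padded by 1 percent.
#' @param tolerance Convergence threshold on `max |delta f|`.
#' @param max_iter Iteration cap; non-convergence is an error reporting
#'   the last `max |delta f|`.
#' @return Object of class `wham_state` with bin edges/centers, the
#'   per-replica histogram matrix, the converged shifts `f`, the
#'   (unnormalised) density of states `omega`, and convergence info.
#' @export
wham_solve <- function(ensemble, n_energy_bins = 200L, tolerance = 1e-7,
                       max_iter = 1e5L) {
  temps <- ensemble$temperatures_K
  betas <- 1 / (kB_kcal * temps)
  energies <- lapply(ensemble$samples, function(s) s$energy)
  pooled <- unlist(energies)
  rng <- range(pooled)
  pad <- max(diff(rng) * 0.01, 1e-6)
  edges <- seq(rng[1L] - pad, rng[2L] + pad, length.out = n_energy_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  R <- length(temps)
  H <- t(vapply(energies, function(e) {
    tabulate(findInterval(e, edges, rightmost.closed = TRUE),
             nbins = n_energy_bins)
  }, integer(n_energy_bins)))
  N <- rowSums(H)
  # adjacent-replica overlap warning
  occ <- H > 0
  for (i in seq_len(R - 1L)) {
    if (!any(occ[i, ] & occ[i + 1L, ]))
      warning(sprintf("no energy-histogram overlap between replicas %d and %d",
                      i, i + 1L))
  }
  e0 <- min(centers)   # shift for numerical stability; cancels in f
  B <- exp(-outer(betas, centers - e0))   # R x nbins Boltzmann factors
  f <- numeric(R)
  m <- colSums(H)
  it <- 0L; max_df <- Inf
  while (it < max_iter) {
    it <- it + 1L
    denom <- colSums((N * exp(f)) * B)    # sum_i N_i exp(f_i) exp(-beta_i E)
    omega <- ifelse(m > 0, m / denom, 0)
    z <- as.vector(B %*% omega)           # exp(-f_new)
    f_new <- -log(z)
    f_new <- f_new - f_new[1L]
    max_df <- max(abs(f_new - f))
    f <- f_new
    if (max_df <= tolerance) break
  }
  if (max_df > tolerance)
    stop(sprintf("WHAM did not converge in %d iterations (max |delta f| = %.3g)",
                 as.integer(max_iter), max_df))
  structure(list(edges = edges, centers = centers, histograms = H,
                 sample_counts = N, betas = betas, temperatures_K = temps,
                 f = f, omega = omega, energy_shift = e0,
                 n_iter = it, max_df = max_df, tolerance = tolerance),
            class = "wham_state")
}

#' @export
print.wham_state <- function(x, ...) {
  cat(sprintf("wham_state: %d replicas, %d bins, converged in %d iterations (max|df| = %.2g)\n",
              length(x$f), length(x$centers), x$n_iter, x$max_df))
  invisible(x)
}

# per-sample WHAM reweighting denominators (T-independent part):
# D_s = sum_j N_j exp(f_j) exp(-beta_j (E_s - e0))
.wham_sample_denominators <- function(wham, energy) {
  de <- energy - wham$energy_shift
  out <- numeric(length(de))
  for (j in seq_along(wham$f)) {
    out <- out + wham$sample_counts[j] * exp(wham$f[j] - wham$betas[j] * de)
  }
  out
}

# normalised sample weights at evaluation temperature
.wham_weights <- function(wham, energy, T_eval) {
  beta <- 1 / (kB_kcal * T_eval)
  w <- exp(-beta * (energy - wham$energy_shift)) /
    .wham_sample_denominators(wham, energy)
  w / sum(w)
}

#' Free-energy surface over one or two reaction coordinates
#'
#' WHAM-reweights all samples to `T_eval`, histograms the named
#' observable(s), and returns `F = -kB T ln P` with the minimum over
#' occupied bins shifted to zero and empty bins masked.
#'
#' @param ensemble A [replica_ensemble()].
#' @param wham A converged [wham_solve()] result.
#' @param obs_x Observable (column) name for the first axis.
#' @param obs_y Optional second-axis observable name; `NULL` gives a 1D
#'   profile.
#' @param bins Bin count per axis (scalar or length 2), or a list of one
#'   or two explicit edge vectors.
#' @param T_eval Evaluation temperature, K.
#' @return Object of class `free_energy_surface`: axis definitions, the
#'   free-energy array (kcal/mol), the probability array, and the
#'   occupancy mask.
#' @export
free_energy_surface <- function(ensemble, wham, obs_x, obs_y = NULL,
                                bins = 50L, T_eval = 300) {
  grab <- function(nm) {
    lapply(ensemble$samples, function(s) {
      if (!nm %in% names(s)) stop("unknown observable: ", nm)
      s[[nm]]
    })
  }
  x <- unlist(grab(obs_x))
  energy <- unlist(lapply(ensemble$samples, function(s) s$energy))
  w <- .wham_weights(wham, energy, T_eval)
  mk_edges <- function(v, nb) {
    r <- range(v)
    pad <- max(diff(r) * 0.001, 1e-9)
    seq(r[1L] - pad, r[2L] + pad, length.out = nb + 1L)
  }
  if (is.list(bins)) {
    ex <- bins[[1L]]
    ey <- if (length(bins) > 1L) bins[[2L]] else NULL
  } else {
    nb <- rep_len(bins, 2L)
    ex <- mk_edges(x, nb[1L])
    ey <- NULL
  }
  kT <- kB_kcal * T_eval
  if (is.null(obs_y)) {
    ix <- findInterval(x, ex, rightmost.closed = TRUE)
    ok <- ix >= 1L & ix <= length(ex) - 1L
    P <- vapply(seq_len(length(ex) - 1L),
                function(b) sum(w[ok & ix == b]), numeric(1))
    occupied <- P > 0
    F <- ifelse(occupied, -kT * log(P), NA_real_)
    F <- F - min(F, na.rm = TRUE)
    return(structure(list(obs_x = obs_x, obs_y = NULL,
                          x_edges = ex, y_edges = NULL,
                          x_centers = (ex[-1L] + ex[-length(ex)]) / 2,
                          probability = P, free_energy = F,
                          occupied = occupied, T_eval = T_eval),
                     class = "free_energy_surface"))
  }
  y <- unlist(grab(obs_y))
  if (is.null(ey)) {
    nb_y <- if (is.list(bins)) 50L else rep_len(bins, 2L)[2L]
    ey <- mk_edges(y, nb_y)
  }
  ix <- findInterval(x, ex, rightmost.closed = TRUE)
  iy <- findInterval(y, ey, rightmost.closed = TRUE)
  nx <- length(ex) - 1L; ny <- length(ey) - 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  P <- matrix(0, nx, ny)
  idx <- cbind(ix[ok], iy[ok])
  agg <- stats::aggregate(w[ok], by = list(ix = idx[, 1L], iy = idx[, 2L]), FUN = sum)
  P[cbind(agg$ix, agg$iy)] <- agg$x
  occupied <- P > 0
  F <- ifelse(occupied, -kT * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  structure(list(obs_x = obs_x, obs_y = obs_y,
                 x_edges = ex, y_edges = ey,
                 x_centers = (ex[-1L] + ex[-length(ex)]) / 2,
                 y_centers = (ey[-1L] + ey[-length(ey)]) / 2,
                 probability = P, free_energy = F,
                 occupied = occupied, T_eval = T_eval),
            class = "free_energy_surface")
}

#' Export a free-energy surface as CSV
#'
#' Columns `x_center[,y_center],F_kcal_mol,occupied`.
#'
#' @param fes A [free_energy_surface()].
#' @param path CSV path.
#' @export
write_surface <- function(fes, path) {
  if (is.null(fes$obs_y)) {
    df <- data.frame(x_center = fes$x_centers,
                     F_kcal_mol = fes$free_energy,
                     occupied = fes$occupied)
  } else {
    grid <- expand.grid(xi = seq_along(fes$x_centers),
                        yi = seq_along(fes$y_centers))
    df <- data.frame(x_center = fes$x_centers[grid$xi],
                     y_center = fes$y_centers[grid$yi],
                     F_kcal_mol = fes$free_energy[cbind(grid$xi, grid$yi)],
                     occupied = fes$occupied[cbind(grid$xi, grid$yi)])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Specific heat curve and melting temperature
#'
#' `Cv(T) = (<E^2>_T - <E>_T^2) / (kB T^2)` with moments from WHAM
#' reweighting of all samples; the melting temperature is the scan argmax
#' (ties broken toward the lowest temperature). A warning flag is set on
#' the curve when the scan extends beyond half/double the sampled ladder.
#'
#' @param ensemble A [replica_ensemble()].
#' @param wham A converged [wham_solve()] result.
#' @param T_scan Temperature grid to evaluate, K (default: ladder range
#'   at 1 K resolution).
#' @return Object of class `thermo_curve` with `temperatures`, `cv`
#'   (kcal/(mol K)) and `tm` (K).
#' @export
specific_heat_curve <- function(ensemble, wham, T_scan = NULL) {
  temps <- ensemble$temperatures_K
  if (is.null(T_scan))
    T_scan <- seq(floor(min(temps)), ceiling(max(temps)), by = 1)
  out_of_range <- any(T_scan < min(temps) / 2 | T_scan > max(temps) * 2)
  if (out_of_range)
    warning("scan extends far outside the sampled temperature ladder")
  energy <- unlist(lapply(ensemble$samples, function(s) s$energy))
  D <- .wham_sample_denominators(wham, energy)
  de <- energy - wham$energy_shift
  cv <- vapply(T_scan, function(T) {
    w <- exp(-de / (kB_kcal * T)) / D
    w <- w / sum(w)
    m1 <- sum(w * energy)
    m2 <- sum(w * energy^2)
    max((m2 - m1^2), 0) / (kB_kcal * T^2)
  }, numeric(1))
  tm <- T_scan[which.max(cv)]   # which.max takes the first (lowest T) tie
  structure(list(temperatures = T_scan, cv = cv, tm = tm,
                 out_of_range = out_of_range),
            class = "thermo_curve")
}

#' @export
print.thermo_curve <- function(x, ...) {
  cat(sprintf("thermo_curve: %d temperatures, Cv peak %.4g kcal/(mol K) at Tm = %g K\n",
              length(x$temperatures), max(x$cv), x$tm))
  invisible(x)
}

#' Export a specific-heat curve as CSV
#'
#' Columns `T_K,Cv`.
#'
#' @param curve A `thermo_curve`.
#' @param path CSV path.
#' @export
write_cv_curve <- function(curve, path) {
  utils::write.csv(data.frame(T_K = curve$temperatures, Cv = curve$cv),
                   path, row.names = FALSE)
  invisible(path)
}

#' Closed-form two-state thermodynamics
#'
#' Reference quantities for the synthetic two-state system of
#' [synth_two_state_ensemble()]: free-energy difference
#' `delta_F(T) = delta_E - kB T ln g` (unfolded minus folded), the exact
#' specific heat `Cv(T) = delta_E^2 p (1 - p) / (kB T^2)` with
#' `p = 1 / (1 + g exp(-delta_E / kB T))`, and the exact Cv-peak
#' temperature found by scanning. These closed forms are independent of
#' the WHAM machinery and serve as its oracle.
#'
#' @param delta_E Energy gap, kcal/mol.
#' @param g Unfolded-state degeneracy.
#' @param T Temperature(s), K.
#' @return `two_state_delta_F` and `two_state_cv` return numerics;
#'   `two_state_cv_peak` returns the peak temperature, K.
#' @export
two_state_delta_F <- function(delta_E, g, T) delta_E - kB_kcal * T * log(g)

#' @rdname two_state_delta_F
#' @export
two_state_cv <- function(delta_E, g, T) {
  p <- 1 / (1 + g * exp(-delta_E / (kB_kcal * T)))
  delta_E^2 * p * (1 - p) / (kB_kcal * T^2)
}

#' @rdname two_state_delta_F
#' @export
two_state_cv_peak <- function(delta_E, g) {
  opt <- stats::optimize(function(T) -two_state_cv(delta_E, g, T),
                         interval = c(1, 2000))
  opt$minimum
}
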