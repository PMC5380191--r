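#' Monte Carlo configuration
#'
#' @param temperature_K Temperature, K (> 0).
#' @param n_steps Number of MC steps (>= 1).
#' @param step_size_deg Half-width of the uniform angular proposal,
#'   degrees in (0, 180].
#' @param seed Integer RNG seed (every stochastic run requires one).
#' @param report_stride Record every `report_stride`-th step.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(temperature_K = 300, n_steps = 10000L,
                      step_size_deg = 30, seed, report_stride = 1L) {
  if (temperature_K <= 0) stop("temperature must be positive")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (step_size_deg <= 0 || step_size_deg > 180)
    stop("step_size_deg must lie in (0, 180]")
  if (missing(seed)) stop("an explicit seed is required")
  structure(list(temperature_K = temperature_K, n_steps = as.integer(n_steps),
                 step_size_deg = step_size_deg, seed = as.integer(seed),
                 report_stride = as.integer(report_stride)),
            class = "mc_config")
}

# wrap angle(s) into (-180, 180]
.wrap_deg <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x == -180] <- 180
  x
}

# fast scalar surface evaluator bound to one coefficient set
.surface_eval1 <- function(coeffs) {
  M <- coeffs$max_order
  ms <- 0:M
  ccc <- coeffs$c_cc; ccs <- coeffs$c_cs
  csc <- coeffs$c_sc; css <- coeffs$c_ss
  k <- pi / 180
  function(phi, psi) {
    ap <- ms * (phi * k); aq <- ms * (psi * k)
    cp <- cos(ap); sp <- sin(ap); cq <- cos(aq); sq <- sin(aq)
    sum(cp * (ccc %*% cq)) + sum(cp * (ccs %*% sq)) +
      sum(sp * (csc %*% cq)) + sum(sp * (css %*% sq))
  }
}

#' Metropolis Monte Carlo on a torsion surface
#'
#' Samples the Boltzmann distribution of a 2D torsion surface with joint
#' uniform angular proposals (periodic wrap on both angles) and the
#' Metropolis acceptance rule `min(1, exp(-dE / kB T))`. Deterministic
#' under a fixed seed.
#'
#' @param coeffs A [fourier_coefficients()].
#' @param config An [mc_config()].
#' @param start Numeric `c(phi, psi)` starting point, degrees.
#' @return Data frame with `step`, `phi`, `psi`, `energy` (recorded every
#'   `report_stride` steps), with the acceptance rate in attribute
#'   `acceptance_rate`.
#' @export
metropolis_mc <- function(coeffs, config, start = c(0, 0)) {
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  chain <- .mc_run(coeffs, config$temperature_K, config$n_steps,
                   config$step_size_deg, config$report_stride, start)
  chain
}

# core MC kernel; assumes RNG state is already set
.mc_run <- function(coeffs, temperature_K, n_steps, step_size_deg,
                    report_stride, start) {
  ev <- .surface_eval1(coeffs)
  beta <- 1 / (kB_kcal * temperature_K)
  n <- n_steps
  dphi <- stats::runif(n, -step_size_deg, step_size_deg)
  dpsi <- stats::runif(n, -step_size_deg, step_size_deg)
  logu <- log(stats::runif(n))
  phi <- start[1L]; psi <- start[2L]
  e <- ev(phi, psi)
  n_rec <- n %/% report_stride
  out_phi <- numeric(n_rec); out_psi <- numeric(n_rec)
  out_e <- numeric(n_rec); out_step <- integer(n_rec)
  acc <- 0L; rec <- 0L
  for (i in seq_len(n)) {
    php <- phi + dphi[i]
    psp <- psi + dpsi[i]
    if (php > 180) php <- php - 360 else if (php <= -180) php <- php + 360
    if (psp > 180) psp <- psp - 360 else if (psp <= -180) psp <- psp + 360
    ep <- ev(php, psp)
    if (logu[i] <= -beta * (ep - e)) {
      phi <- php; psi <- psp; e <- ep
      acc <- acc + 1L
    }
    if (i %% report_stride == 0L) {
      rec <- rec + 1L
      out_phi[rec] <- phi; out_psi[rec] <- psi
      out_e[rec] <- e; out_step[rec] <- i
    }
  }
  res <- data.frame(step = out_step, phi = out_phi, psi = out_psi,
                    energy = out_e)
  attr(res, "acceptance_rate") <- acc / n
  res
}

#' Named temperature ladders
#'
#' The two 12-replica ladders used as default configurations, keyed
#' `"2i9m"` (helical peptide study) and `"trpzip2"` (beta-hairpin study).
#'
#' @param name Ladder name.
#' @return Numeric vector of temperatures, K, increasing.
#' @export
temperature_ladder <- function(name = c("2i9m", "trpzip2")) {
  name <- match.arg(name)
  switch(name,
    "2i9m" = c(267.0, 283.0, 300.0, 328.0, 353.0, 380.0, 409.0, 439.0,
               471.0, 506.0, 542.0, 577.0),
    "trpzip2" = c(255.00, 277.09, 300.63, 325.74, 352.50, 381.04, 411.51,
                  443.96, 478.65, 515.62, 555.04, 597.08))
}

#' Replica ensemble container
#'
#' Per-temperature sample tables plus exchange statistics, the common
#' input of the WHAM module.
#'
#' @param temperatures_K Strictly increasing temperatures, K.
#' @param samples List (one per temperature) of data frames; each must
#'   contain an `energy` column (kcal/mol) and may carry observables.
#' @param exchange_stats Optional data frame of per-neighbor-pair
#'   `attempted` / `accepted` counts.
#' @param metadata Optional named list.
#' @return Object of class `replica_ensemble`.
#' @export
replica_ensemble <- function(temperatures_K, samples, exchange_stats = NULL,
                             metadata = list()) {
  if (any(diff(temperatures_K) <= 0))
    stop("temperatures must be strictly increasing")
  if (length(samples) != length(temperatures_K))
    stop("one sample table per temperature")
  for (s in samples) {
    if (!is.data.frame(s) || nrow(s) == 0L || !("energy" %in% names(s)))
      stop("each sample table must be a non-empty data frame with an energy column")
  }
  if (!is.null(exchange_stats) &&
      any(exchange_stats$accepted > exchange_stats$attempted))
    stop("accepted counts cannot exceed attempts")
  structure(list(temperatures_K = temperatures_K, samples = samples,
                 exchange_stats = exchange_stats, metadata = metadata),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat(sprintf("replica_ensemble: %d replicas (%g..%g K), %d samples each\n",
              length(x$temperatures_K), min(x$temperatures_K),
              max(x$temperatures_K), nrow(x$samples[[1L]])))
  invisible(x)
}

#' Replica-exchange Monte Carlo on a torsion surface
#'
#' Runs one Metropolis walker per temperature and attempts neighbor swaps
#' every `swap_interval` steps with acceptance
#' `min(1, exp((beta_i - beta_j)(E_i - E_j)))`, alternating even/odd
#' neighbor pairing between successive attempts. Per-pair exchange
#' statistics are recorded. Deterministic under a fixed seed.
#'
#' @param coeffs A [fourier_coefficients()].
#' @param temperatures_K Ladder of >= 2 temperatures, K. Duplicates are
#'   rejected unless `allow_equal = TRUE` (validation mode).
#' @param config An [mc_config()]; `temperature_K` is ignored,
#'   `n_steps` is the per-replica total.
#' @param swap_interval Steps between swap attempts.
#' @param start `c(phi, psi)` start for every replica.
#' @param allow_equal Permit duplicate temperatures.
#' @return A [replica_ensemble()] whose samples carry `step`, `phi`,
#'   `psi`, `energy`.
#' @export
replica_exchange_mc <- function(coeffs, temperatures_K, config,
                                swap_interval = 10L, start = c(0, 0),
                                allow_equal = FALSE) {
  if (length(temperatures_K) < 2L) stop("need at least 2 temperatures")
  if (!allow_equal && anyDuplicated(temperatures_K))
    stop("duplicate temperatures in the ladder")
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  R <- length(temperatures_K)
  betas <- 1 / (kB_kcal * temperatures_K)
  ev <- .surface_eval1(coeffs)
  phi <- rep(start[1L], R); psi <- rep(start[2L], R)
  e <- vapply(seq_len(R), function(i) ev(phi[i], psi[i]), numeric(1))
  n_sweeps <- config$n_steps %/% swap_interval
  rec <- vector("list", R)
  for (i in seq_len(R)) rec[[i]] <- list()
  attempted <- integer(R - 1L); accepted <- integer(R - 1L)
  step0 <- 0L
  sub <- config
  for (sw in seq_len(n_sweeps)) {
    for (i in seq_len(R)) {
      seg <- .mc_run(coeffs, temperatures_K[i], swap_interval,
                     config$step_size_deg, config$report_stride,
                     c(phi[i], psi[i]))
      if (nrow(seg) > 0L) {
        seg$step <- seg$step + step0
        rec[[i]][[sw]] <- seg
      }
      last <- if (nrow(seg) > 0L) seg[nrow(seg), ] else NULL
      # track current state exactly (stride may skip the final step)
      phi[i] <- if (!is.null(last)) last$phi else phi[i]
      psi[i] <- if (!is.null(last)) last$psi else psi[i]
      e[i] <- ev(phi[i], psi[i])
    }
    step0 <- step0 + swap_interval
    first <- if (sw %% 2L == 1L) 1L else 2L
    pairs <- if (first > R - 1L) integer(0) else seq(first, R - 1L, by = 2L)
    for (i in pairs) {
      j <- i + 1L
      attempted[i] <- attempted[i] + 1L
      log_acc <- (betas[i] - betas[j]) * (e[i] - e[j])
      if (log(stats::runif(1L)) <= log_acc) {
        accepted[i] <- accepted[i] + 1L
        tmp <- c(phi[i], psi[i], e[i])
        phi[i] <- phi[j]; psi[i] <- psi[j]; e[i] <- e[j]
        phi[j] <- tmp[1L]; psi[j] <- tmp[2L]; e[j] <- tmp[3L]
      }
    }
  }
  samples <- lapply(rec, function(x) do.call(rbind, x))
  stats_df <- data.frame(pair = paste(seq_len(R - 1L), 2:R, sep = "-"),
                         attempted = attempted, accepted = accepted)
  replica_ensemble(if (allow_equal) temperatures_K + seq_len(R) * 1e-9
                   else temperatures_K,
                   samples, exchange_stats = stats_df,
                   metadata = list(swap_interval = swap_interval,
                                   seed = config$seed))
}

#' Synthetic two-state thermodynamic ensemble
#'
#' Independent draws from an exactly solvable two-state system: a unique
#' folded state at energy 0 and a `g`-fold degenerate unfolded state at
#' `delta_E`. At temperature T a sample is folded with probability
#' `1 / (1 + g exp(-delta_E / kB T))`. The temperature at which the folded
#' fraction crosses 1/2, `delta_E / (kB ln g)`, is recorded in the
#' metadata as `tm_analytic`. Used as analytic ground truth for the WHAM
#' and specific-heat machinery.
#'
#' @param delta_E Unfolding energy gap, kcal/mol (> 0).
#' @param g_unfolded Degeneracy of the unfolded state (integer >= 2).
#' @param temperatures_K Ladder of temperatures, K.
#' @param n_per_T Samples per temperature.
#' @param seed Integer RNG seed.
#' @return A [replica_ensemble()] whose samples carry `step`, `energy`
#'   and the binary observable `folded`.
#' @export
synth_two_state_ensemble <- function(delta_E, g_unfolded, temperatures_K,
                                     n_per_T, seed) {
  if (delta_E <= 0) stop("delta_E must be positive")
  if (g_unfolded < 2) stop("g_unfolded must be >= 2")
  set.seed(seed)
  samples <- lapply(temperatures_K, function(T) {
    p_fold <- 1 / (1 + g_unfolded * exp(-delta_E / (kB_kcal * T)))
    folded <- stats::runif(n_per_T) < p_fold
    data.frame(step = seq_len(n_per_T),
               energy = ifelse(folded, 0, delta_E),
               folded = as.integer(folded))
  })
  replica_ensemble(temperatures_K, samples,
                   metadata = list(delta_E = delta_E, g_unfolded = g_unfolded,
                                   tm_analytic = delta_E / (kB_kcal * log(g_unfolded)),
                                   seed = seed))
}

#' Write / read a replica ensemble as per-replica CSV files
#'
#' Each replica table goes to `<prefix>_replica<k>.csv`
#' (columns `step,energy,...`); the ladder goes to
#' `<prefix>_temperatures.csv`.
#'
#' @param ensemble A [replica_ensemble()].
#' @param prefix Path prefix.
#' @export
write_ensemble <- function(ensemble, prefix) {
  utils::write.csv(data.frame(replica = seq_along(ensemble$temperatures_K),
                              temperature_K = ensemble$temperatures_K),
                   paste0(prefix, "_temperatures.csv"), row.names = FALSE)
  for (k in seq_along(ensemble$samples)) {
    utils::write.csv(ensemble$samples[[k]],
                     sprintf("%s_replica%d.csv", prefix, k), row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(prefix) {
  tf <- paste0(prefix, "_temperatures.csv")
  if (!file.exists(tf)) stop("missing ", tf)
  tt <- utils::read.csv(tf)
  samples <- lapply(seq_len(nrow(tt)), function(k) {
    utils::read.csv(sprintf("%s_replica%d.csv", prefix, k))
  })
  replica_ensemble(tt$temperature_K, samples)
}
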