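#' Tabulated backbone torsion energy grid
#'
#' A `torsion_grid` stores energies (kcal/mol) on a regular (phi, psi)
#' lattice whose spacing divides 360 degrees exactly (left-closed periodic
#' lattice, e.g. -180, -165, ..., 165 for 24 points at 15 degrees).
#' Optional component matrices record the decomposition the grid came
#' from: total target energy `e_qm`, non-torsion internal terms `e_other`,
#' and solvation free energy `g_solv`.
#'
#' @param phi_values,psi_values Strictly increasing, uniformly spaced
#'   degrees.
#' @param energy Matrix indexed \[phi, psi\], kcal/mol.
#' @param components Optional named list of matrices (`e_qm`, `e_other`,
#'   `g_solv`).
#' @param offset Energy offset subtracted when the minimum was shifted to
#'   zero (kcal/mol).
#' @return Object of class `torsion_grid`.
#' @export
torsion_grid <- function(phi_values, psi_values, energy,
                         components = NULL, offset = 0) {
  energy <- as.matrix(energy)
  .check_axis <- function(v, nm) {
    if (length(v) < 2L || any(diff(v) <= 0)) stop(nm, " must be strictly increasing")
    h <- diff(v)
    if (max(abs(h - h[1L])) > 1e-9) stop(nm, " must be uniformly spaced")
    if (abs(360 / h[1L] - round(360 / h[1L])) > 1e-9)
      stop(nm, " spacing must divide 360 degrees exactly")
  }
  .check_axis(phi_values, "phi_values")
  .check_axis(psi_values, "psi_values")
  if (nrow(energy) != length(phi_values) || ncol(energy) != length(psi_values))
    stop("energy matrix shape must be length(phi) x length(psi)")
  if (!all(is.finite(energy))) stop("non-finite grid energies")
  structure(list(phi_values = phi_values, psi_values = psi_values,
                 energy = energy, components = components, offset = offset),
            class = "torsion_grid")
}

#' Decompose an energy grid into the 2D torsion correction
#'
#' The coupled torsion term is what remains of the target total energy
#' after removing the non-torsion internal terms and the solvation free
#' energy: `energy = e_qm - e_other - g_solv`, elementwise. The global
#' minimum is shifted to zero and the shift recorded as `offset`.
#'
#' @param e_qm,e_other,g_solv Matrices of equal shape, kcal/mol.
#' @inheritParams torsion_grid
#' @return A [torsion_grid()] with components stored.
#' @export
decompose_grid <- function(e_qm, e_other, g_solv, phi_values, psi_values) {
  e_qm <- as.matrix(e_qm); e_other <- as.matrix(e_other)
  g_solv <- as.matrix(g_solv)
  if (!identical(dim(e_qm), dim(e_other)) || !identical(dim(e_qm), dim(g_solv)))
    stop("component matrices must share one grid shape")
  e <- e_qm - e_other - g_solv
  off <- min(e)
  torsion_grid(phi_values, psi_values, e - off,
               components = list(e_qm = e_qm, e_other = e_other,
                                 g_solv = g_solv),
               offset = off)
}

#' Double Fourier coefficients of a torsion surface
#'
#' Holds the four coefficient matrices of the expansion
#' `E(phi, psi) = sum_{m,n} c_cc cos(m phi) cos(n psi) +
#' c_cs cos(m phi) sin(n psi) + c_sc sin(m phi) cos(n psi) +
#' c_ss sin(m phi) sin(n psi)`, each of shape (M+1) x (M+1), kcal/mol.
#' Rows with m = 0 of `c_sc`/`c_ss` and columns with n = 0 of
#' `c_cs`/`c_ss` are structural zeros (the zero-order sine vanishes).
#'
#' @param max_order Integer truncation order M.
#' @param c_cc,c_cs,c_sc,c_ss (M+1) x (M+1) matrices; missing entries
#'   default to zero.
#' @return Object of class `fourier_coefficients`.
#' @export
fourier_coefficients <- function(max_order, c_cc = NULL, c_cs = NULL,
                                 c_sc = NULL, c_ss = NULL) {
  M <- as.integer(max_order)
  if (M < 0L) stop("max_order must be >= 0")
  z <- matrix(0, M + 1L, M + 1L)
  fill <- function(x) {
    if (is.null(x)) return(z)
    x <- as.matrix(x)
    if (!identical(dim(x), dim(z))) stop("coefficient matrices must be (M+1) x (M+1)")
    if (!all(is.finite(x))) stop("non-finite coefficients")
    unname(x)
  }
  c_cc <- fill(c_cc); c_cs <- fill(c_cs); c_sc <- fill(c_sc); c_ss <- fill(c_ss)
  c_sc[1L, ] <- 0; c_ss[1L, ] <- 0    # m = 0
  c_cs[, 1L] <- 0; c_ss[, 1L] <- 0    # n = 0
  structure(list(max_order = M, c_cc = c_cc, c_cs = c_cs,
                 c_sc = c_sc, c_ss = c_ss),
            class = "fourier_coefficients")
}

#' @export
print.fourier_coefficients <- function(x, ...) {
  cat(sprintf("fourier_coefficients: max_order = %d\n", x$max_order))
  invisible(x)
}

# design matrix of the tensor trigonometric basis at (phi, psi) in degrees;
# returns list(X, cols) where cols is a data.frame(type, m, n)
.fourier_design <- function(phi_deg, psi_deg, M) {
  p <- phi_deg * pi / 180
  q <- psi_deg * pi / 180
  ms <- 0:M
  CP <- outer(p, ms, function(a, m) cos(m * a))
  SP <- outer(p, ms, function(a, m) sin(m * a))
  CQ <- outer(q, ms, function(a, m) cos(m * a))
  SQ <- outer(q, ms, function(a, m) sin(m * a))
  cols <- list(); blocks <- list()
  for (type in c("cc", "cs", "sc", "ss")) {
    mr <- if (type %in% c("sc", "ss")) 1:M else 0:M
    nr <- if (type %in% c("cs", "ss")) 1:M else 0:M
    if (M == 0L && type != "cc") next
    P <- if (type %in% c("sc", "ss")) SP else CP
    Q <- if (type %in% c("cs", "ss")) SQ else CQ
    for (m in mr) for (n in nr) {
      blocks[[length(blocks) + 1L]] <- P[, m + 1L] * Q[, n + 1L]
      cols[[length(cols) + 1L]] <- data.frame(type = type, m = m, n = n)
    }
  }
  list(X = do.call(cbind, blocks), cols = do.call(rbind, cols))
}

#' Fit a double Fourier series to a torsion grid
#'
#' Ordinary least squares over the tensor-product trigonometric basis up
#' to `max_order` in each of phi and psi. On the uniform periodic lattice
#' the basis is orthogonal, so a surface lying in the basis span is
#' recovered exactly (to numerical precision). Structural zero
#' coefficients are exactly zero by construction.
#'
#' @param grid A [torsion_grid()].
#' @param max_order Truncation order M; must satisfy the aliasing bound
#'   `M <= floor((n_grid - 1) / 2)` on each axis.
#' @return A [fourier_coefficients()].
#' @export
fit_fourier <- function(grid, max_order) {
  M <- as.integer(max_order)
  nb <- min(length(grid$phi_values), length(grid$psi_values))
  bound <- (nb - 1L) %/% 2L
  if (M > bound)
    stop(sprintf(
      "max_order %d exceeds the aliasing bound floor((n_grid - 1)/2) = %d for %d grid points",
      M, bound, nb))
  nodes <- expand.grid(phi = grid$phi_values, psi = grid$psi_values)
  y <- as.vector(grid$energy)  # column-major: phi varies fastest, matches expand.grid
  des <- .fourier_design(nodes$phi, nodes$psi, M)
  beta <- qr.coef(qr(des$X), y)
  beta[is.na(beta)] <- 0
  out <- fourier_coefficients(M)
  for (j in seq_along(beta)) {
    slot <- paste0("c_", des$cols$type[j])
    out[[slot]][des$cols$m[j] + 1L, des$cols$n[j] + 1L] <- beta[j]
  }
  out
}

#' Evaluate the smooth torsion surface
#'
#' @param coeffs A [fourier_coefficients()].
#' @param phi,psi Angles in degrees (vectorised, recycled to a common
#'   length); the surface is exactly 360-degree periodic in both.
#' @return Energy in kcal/mol.
#' @export
evaluate_surface <- function(coeffs, phi, psi) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n) * pi / 180
  psi <- rep_len(psi, n) * pi / 180
  ms <- 0:coeffs$max_order
  CP <- outer(phi, ms, function(a, m) cos(m * a))
  SP <- outer(phi, ms, function(a, m) sin(m * a))
  CQ <- outer(psi, ms, function(a, m) cos(m * a))
  SQ <- outer(psi, ms, function(a, m) sin(m * a))
  rowSums((CP %*% coeffs$c_cc) * CQ) + rowSums((CP %*% coeffs$c_cs) * SQ) +
    rowSums((SP %*% coeffs$c_sc) * CQ) + rowSums((SP %*% coeffs$c_ss) * SQ)
}

#' Analytic partial derivatives of the torsion surface
#'
#' Term-by-term differentiation of the double Fourier series. Inputs are
#' degrees; derivatives are reported per radian (kcal/mol/rad), the form
#' needed by the chain rule for Cartesian forces.
#'
#' @inheritParams evaluate_surface
#' @return List with numeric vectors `dphi` and `dpsi`, kcal/mol/radian.
#' @export
surface_partials <- function(coeffs, phi, psi) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n) * pi / 180
  psi <- rep_len(psi, n) * pi / 180
  ms <- 0:coeffs$max_order
  CP <- outer(phi, ms, function(a, m) cos(m * a))
  SP <- outer(phi, ms, function(a, m) sin(m * a))
  CQ <- outer(psi, ms, function(a, m) cos(m * a))
  SQ <- outer(psi, ms, function(a, m) sin(m * a))
  mCP <- sweep(CP, 2L, ms, `*`)   # m * cos(m phi)
  mSP <- sweep(SP, 2L, ms, `*`)
  nCQ <- sweep(CQ, 2L, ms, `*`)
  nSQ <- sweep(SQ, 2L, ms, `*`)
  dphi <- rowSums((-mSP %*% coeffs$c_cc) * CQ) +
    rowSums((-mSP %*% coeffs$c_cs) * SQ) +
    rowSums((mCP %*% coeffs$c_sc) * CQ) +
    rowSums((mCP %*% coeffs$c_ss) * SQ)
  dpsi <- rowSums((CP %*% coeffs$c_cc) * (-nSQ)) +
    rowSums((CP %*% coeffs$c_cs) * nCQ) +
    rowSums((SP %*% coeffs$c_sc) * (-nSQ)) +
    rowSums((SP %*% coeffs$c_ss) * nCQ)
  list(dphi = dphi, dpsi = dpsi)
}

#' Write / read Fourier coefficients as a text parameter file
#'
#' Line 1 is the header `TORSION2D v1 max_order=M units=kcal/mol`,
#' followed by one line `m n c_cc c_cs c_sc c_ss` per coefficient pair
#' (all 0 <= m, n <= M), written with 17 significant digits so the
#' round trip is exact on the decimal representation.
#'
#' @param coeffs A [fourier_coefficients()].
#' @param path File path.
#' @return `write_coefficients` returns `path` invisibly;
#'   `read_coefficients` returns a [fourier_coefficients()].
#' @export
write_coefficients <- function(coeffs, path) {
  M <- coeffs$max_order
  lines <- sprintf("TORSION2D v1 max_order=%d units=kcal/mol", M)
  for (m in 0:M) for (n in 0:M) {
    lines <- c(lines, sprintf("%d %d %.17g %.17g %.17g %.17g", m, n,
                              coeffs$c_cc[m + 1L, n + 1L],
                              coeffs$c_cs[m + 1L, n + 1L],
                              coeffs$c_sc[m + 1L, n + 1L],
                              coeffs$c_ss[m + 1L, n + 1L]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hd <- regmatches(lines[1L],
                   regexec("^TORSION2D v1 max_order=(\\d+) units=kcal/mol$", lines[1L]))[[1L]]
  if (length(hd) != 2L)
    stop("line 1: malformed TORSION2D header")
  M <- as.integer(hd[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != (M + 1L)^2)
    stop(sprintf("expected %d coefficient lines, found %d", (M + 1L)^2, length(body)))
  out <- fourier_coefficients(M)
  for (k in seq_along(body)) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1L]]
    if (length(f) != 6L)
      stop(sprintf("line %d: expected 6 columns, found %d", k + 1L, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("line %d: non-numeric entry", k + 1L))
    m <- as.integer(v[1L]); n <- as.integer(v[2L])
    if (m > M || n > M) stop(sprintf("line %d: order out of range", k + 1L))
    out$c_cc[m + 1L, n + 1L] <- v[3L]
    out$c_cs[m + 1L, n + 1L] <- v[4L]
    out$c_sc[m + 1L, n + 1L] <- v[5L]
    out$c_ss[m + 1L, n + 1L] <- v[6L]
  }
  fourier_coefficients(M, out$c_cc, out$c_cs, out$c_sc, out$c_ss)
}

#' Write / read a torsion grid as CSV
#'
#' Columns `phi_deg,psi_deg,energy` plus optional `e_qm,e_other,g_solv`
#' components; one row per node, row-major in phi then psi.
#'
#' @param grid A [torsion_grid()].
#' @param path CSV path.
#' @export
write_torsion_grid <- function(grid, path) {
  nodes <- expand.grid(psi_deg = grid$psi_values, phi_deg = grid$phi_values)
  df <- data.frame(phi_deg = nodes$phi_deg, psi_deg = nodes$psi_deg)
  idx <- cbind(match(df$phi_deg, grid$phi_values),
               match(df$psi_deg, grid$psi_values))
  df$energy <- grid$energy[idx]
  for (nm in names(grid$components)) df[[nm]] <- grid$components[[nm]][idx]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_torsion_grid
#' @export
read_torsion_grid <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("phi_deg", "psi_deg", "energy") %in% names(df)))
    stop("grid CSV needs columns phi_deg, psi_deg, energy")
  phis <- sort(unique(df$phi_deg)); psis <- sort(unique(df$psi_deg))
  if (nrow(df) != length(phis) * length(psis))
    stop("grid CSV is not a complete lattice")
  idx <- cbind(match(df$phi_deg, phis), match(df$psi_deg, psis))
  E <- matrix(NA_real_, length(phis), length(psis))
  E[idx] <- df$energy
  comp_names <- intersect(c("e_qm", "e_other", "g_solv"), names(df))
  comps <- NULL
  if (length(comp_names) > 0L) {
    comps <- lapply(comp_names, function(nm) {
      m <- matrix(NA_real_, length(phis), length(psis)); m[idx] <- df[[nm]]; m
    })
    names(comps) <- comp_names
  }
  torsion_grid(phis, psis, E, components = comps)
}

#' Sample a coefficient surface onto a regular lattice
#'
#' Utility used throughout the tests and the synthetic-data paths: builds
#' the left-closed periodic lattice with `n` points per axis (spacing
#' 360/n degrees, default the 24-point, 15-degree lattice) and tabulates
#' the surface on it.
#'
#' @param coeffs A [fourier_coefficients()].
#' @param n Points per axis.
#' @return A [torsion_grid()].
#' @export
sample_surface_grid <- function(coeffs, n = 24L) {
  ax <- seq(-180, 180 - 360 / n, by = 360 / n)
  E <- matrix(evaluate_surface(coeffs,
                               rep(ax, times = n), rep(ax, each = n)), n, n)
  torsion_grid(ax, ax, E)
}

#' Draw a random coefficient set
#'
#' Gaussian coefficients with amplitude decaying with total order,
#' structural zeros respected. Used as the synthetic surface generator.
#'
#' @param max_order Truncation order.
#' @param scale Standard deviation of the (m + n = 1) coefficients,
#'   kcal/mol.
#' @return A [fourier_coefficients()].
#' @export
random_coefficients <- function(max_order, scale = 1) {
  M <- as.integer(max_order)
  decay <- outer(0:M, 0:M, function(m, n) scale / (1 + m + n))
  rmat <- function() matrix(stats::rnorm((M + 1L)^2), M + 1L) * decay
  fourier_coefficients(M, rmat(), rmat(), rmat(), rmat())
}
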