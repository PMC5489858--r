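#' Bending force in Fourier space
#'
#' Force per mode from the Canham-Helfrich bending energy
#' `E_b = (B/2) int (laplacian h)^2 dx`, which is diagonal in Fourier space:
#' `F_q = -B q^4 h_q`.
#'
#' @param hq complex spectral field (nm^3).
#' @param grid a [wave_grid()].
#' @param B bending rigidity (pN nm).
#' @return complex force field (pN nm^2 per mode, same transform convention
#'   as the spectral field).
#' @export
bending_force <- function(hq, grid, B) {
  -B * grid$qmag^4 * hq
}

#' Receptor lattice
#'
#' Uniform `Nb x Nb` lattice of receptor-ligand pairs at positions
#' `x_mn = (m Delta, n Delta)`, `m, n = 0, ..., Nb - 1`, registered with the
#' collocation grid so membrane heights at receptor sites need no
#' interpolation.
#'
#' @param config a [sim_config()].
#' @param grid matching [wave_grid()] (built from `config` if missing).
#' @return data.frame with columns `m`, `n`, `x`, `y` (nm) and 1-based grid
#'   indices `ix`, `iy`, in row-major site order (`m` outer, `n` inner).
#' @export
receptor_lattice <- function(config, grid = wave_grid(config)) {
  step <- config$Delta / grid$dx
  if (abs(step - round(step)) > 1e-9)
    stop("receptor spacing Delta is not a multiple of the grid spacing")
  step <- as.integer(round(step))
  m <- rep(0:(config$Nb - 1L), each = config$Nb)
  n <- rep(0:(config$Nb - 1L), times = config$Nb)
  data.frame(m = m, n = n,
             x = m * config$Delta, y = n * config$Delta,
             ix = m * step + 1L, iy = n * step + 1L)
}

#' New bond-state matrix
#' @param Nb receptors per side.
#' @param closed logical or 0/1: initial state of every bond (default open).
#' @return integer `Nb x Nb` matrix of 0 (open) / 1 (closed).
#' @export
bond_state <- function(Nb, closed = FALSE) {
  matrix(as.integer(closed), Nb, Nb)
}

#' Linkage force in Fourier space
#'
#' Each closed bond is a harmonic spring pinning the membrane at its site:
#' `F_q = -sum_mn phi_mn k (h(x_mn) - h_L) exp(-i q.x_mn)`.  The point
#' forces are placed on the collocation grid and transformed by a single
#' DFT (no area factor: delta-function loads).
#'
#' @param h real `N x N` height matrix (nm).
#' @param bonds integer `Nb x Nb` bond-state matrix (`phi_mn`).
#' @param k linkage spring constant (pN/nm).
#' @param h_L rest ligand height (nm).
#' @param lattice a [receptor_lattice()].
#' @param grid a [wave_grid()].
#' @return complex force field.
#' @export
linkage_force <- function(h, bonds, k, h_L, lattice, grid) {
  S <- matrix(0, grid$N, grid$N)
  # bonds is indexed [m + 1, n + 1]; lattice rows are in the same order
  closed <- bonds[cbind(lattice$m + 1L, lattice$n + 1L)] == 1L
  if (any(closed)) {
    ij <- cbind(lattice$ix[closed], lattice$iy[closed])
    S[ij] <- S[ij] - k * (h[ij] - h_L)
  }
  stats::fft(S)
}

#' Pointwise soft-wall repulsive pressure
#'
#' The substrate repulsion `E_w = eps_w int (sigma_w / (h + sigma_w - h_sub))^8 dx`,
#' truncated to zero for `h > h_sub`, exerts the upward pressure
#' `P(h) = 8 (eps_w / sigma_w) (sigma_w / (h + sigma_w - h_sub))^9` where
#' `h <= h_sub` and zero above.  The truncation is applied literally, so the
#' pressure steps from `8 eps_w / sigma_w` to 0 at `h = h_sub`.
#'
#' @param h height(s) (nm), scalar or matrix.
#' @param sigma_w wall length scale (nm).
#' @param eps_w wall strength (pN/nm).
#' @param h_sub truncation height (nm).
#' @return pressure (pN/nm^2), same shape as `h`.
#' @export
wall_pressure <- function(h, sigma_w, eps_w, h_sub = 0) {
  u <- h + sigma_w - h_sub
  if (any(h <= h_sub & u <= 0))
    stop("membrane reached the wall singularity (h <= h_sub - sigma_w); ",
         "the timestep is too large for this wall stiffness")
  P <- ifelse(h <= h_sub, 8 * (eps_w / sigma_w) * (sigma_w / u)^9, 0)
  if (is.matrix(h)) matrix(P, nrow(h), ncol(h)) else P
}

#' Soft-wall force in Fourier space
#'
#' Pseudo-spectral treatment of the nonlinear wall: the pointwise pressure
#' [wall_pressure()] is evaluated on the collocation grid and transformed,
#' `F_q = (L/N)^2 DFT(P)`.
#'
#' @inheritParams wall_pressure
#' @param grid a [wave_grid()].
#' @return complex force field.
#' @export
wall_force <- function(h, grid, sigma_w, eps_w, h_sub = 0) {
  stats::fft(wall_pressure(h, sigma_w, eps_w, h_sub)) * grid$dx^2
}

#' Uniform pressure force
#'
#' A spatially uniform applied pressure `p` contributes only to the zero
#' mode: `F_q = -L^2 p delta_{q,0}`.  Positive `p` pushes the membrane
#' toward the substrate.
#'
#' @param p pressure (pN/nm^2).
#' @param grid a [wave_grid()].
#' @return complex force field.
#' @export
pressure_force <- function(p, grid) {
  F <- spectral_zero(grid)
  F[1, 1] <- -grid$L^2 * p
  F
}

#' Total deterministic force
#'
#' Sum of the enabled force terms.  The free-membrane experiment uses
#' `terms = "bending"`; the entropic-pressure experiment uses bending +
#' wall + pressure; adhesion runs use all four.
#'
#' @param hq spectral field.
#' @param h matching real field (recomputed if `NULL`).
#' @param bonds bond-state matrix (required when `"linkage"` is enabled).
#' @param config a [sim_config()].
#' @param grid a [wave_grid()].
#' @param lattice a [receptor_lattice()] (required for `"linkage"`).
#' @param terms character subset of
#'   `c("bending", "wall", "linkage", "pressure")`.
#' @return complex force field.
#' @export
total_force <- function(hq, h = NULL, bonds = NULL, config, grid,
                        lattice = NULL,
                        terms = c("bending", "wall", "linkage", "pressure")) {
  terms <- match.arg(terms, several.ok = TRUE)
  F <- spectral_zero(grid)
  need_h <- any(c("wall", "linkage") %in% terms)
  if (need_h && is.null(h)) h <- to_real(hq, grid)
  if ("bending" %in% terms)
    F <- F + bending_force(hq, grid, config$B)
  if ("wall" %in% terms)
    F <- F + wall_force(h, grid, config$sigma_w, config$eps_w, config$h_sub)
  if ("linkage" %in% terms) {
    if (is.null(bonds) || is.null(lattice))
      stop("linkage force requires bonds and a receptor lattice")
    F <- F + linkage_force(h, bonds, config$k, config$h_L, lattice, grid)
  }
  if ("pressure" %in% terms)
    F <- F + pressure_force(config$p, grid)
  F
}

#' Bending energy of a spectral field
#' @param hq spectral field.
#' @param grid a [wave_grid()].
#' @param B bending rigidity (pN nm).
#' @return energy (pN nm).
#' @export
bending_energy <- function(hq, grid, B) {
  0.5 * B / grid$L^2 * sum(grid$qmag^4 * Mod(hq)^2)
}

#' Linkage energy of the closed bonds
#' @param h real height matrix.
#' @param bonds bond-state matrix.
#' @param k spring constant (pN/nm).
#' @param h_L rest ligand height (nm).
#' @param lattice a [receptor_lattice()].
#' @return energy (pN nm).
#' @export
linkage_energy <- function(h, bonds, k, h_L, lattice) {
  closed <- bonds[cbind(lattice$m + 1L, lattice$n + 1L)] == 1L
  if (!any(closed)) return(0)
  ij <- cbind(lattice$ix[closed], lattice$iy[closed])
  sum(0.5 * k * (h[ij] - h_L)^2)
}
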