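#' Force on a closed receptor-ligand bond
#'
#' Tension in the linkage spring from the membrane pulling the receptor
#' above the ligand rest height: `f = k * max(h - h_L, 0)`.  Compression is
#' not transmitted to the bond (a slip bond ruptures under tension only),
#' so `f = 0` when `h <= h_L`.
#'
#' @param h_at_site membrane height(s) at the receptor site(s) (nm).
#' @param k linkage spring constant (pN/nm).
#' @param h_L rest ligand height (nm).
#' @return force (pN), vectorised over `h_at_site`.
#' @export
bond_force <- function(h_at_site, k, h_L) {
  k * pmax(h_at_site - h_L, 0)
}

#' Bell-model off-rate
#'
#' Force-accelerated dissociation, `koff = koff0 exp(f x_b / kBT)`.
#'
#' @param f bond force (pN).
#' @param koff0 zero-force off-rate (1/ns).
#' @param x_b Bell length (nm).
#' @param kBT thermal energy (pN nm).
#' @return off-rate (1/ns), vectorised over `f`.
#' @export
bell_off_rate <- function(f, koff0, x_b, kBT) {
  koff0 * exp(f * x_b / kBT)
}

#' Equilibrium closed probability of a two-state bond
#'
#' Detailed balance of the fixed-timestep Monte Carlo scheme: with per-step
#' probabilities `kon0 dt` and `koff dt`, the stationary closed fraction is
#' `kon0 / (kon0 + koff)` independently of `dt`.
#'
#' @param kon0 on-rate (1/ns).
#' @param koff off-rate (1/ns).
#' @return stationary closed probability.
#' @export
two_state_occupancy <- function(kon0, koff) {
  kon0 / (kon0 + koff)
}

#' One Monte Carlo sweep over the receptor lattice
#'
#' Visits every site once.  An open bond closes with probability
#' `kon0 * dt` if the receptor-ligand separation `|h(x_mn) - h_L|` is within
#' the encounter distance `R_RL`; a closed bond opens with probability
#' `koff * dt`, `koff` from [bell_off_rate()] with the [bond_force()] at the
#' site.  Probabilities above 1 are clamped (counted in `n_clamp`).  One
#' uniform draw is taken per site in row-major order (`m` outer, `n`
#' inner), whether or not the site is eligible, which keeps the draw count
#' independent of the state.
#'
#' @param bonds integer `Nb x Nb` bond-state matrix.
#' @param h real `N x N` height matrix.
#' @param config a [sim_config()].
#' @param lattice a [receptor_lattice()].
#' @return list: updated `bonds`, event counts `n_bind`, `n_unbind`,
#'   `n_clamp`.
#' @export
kinetic_sweep <- function(bonds, h, config, lattice) {
  Nb <- config$Nb
  g <- h[cbind(lattice$ix, lattice$iy)]        # row-major site order
  state <- bonds[cbind(lattice$m + 1L, lattice$n + 1L)]
  u <- stats::runif(length(g))

  p_on <- min(config$kon0 * config$dt, 1)
  can_bind <- state == 0L & abs(g - config$h_L) <= config$R_RL
  do_bind <- can_bind & u < p_on

  f <- bond_force(g, config$k, config$h_L)
  p_off <- bell_off_rate(f, config$koff0, config$x_b, config$kBT) * config$dt
  n_clamp <- sum(state == 1L & p_off > 1)
  p_off <- pmin(p_off, 1)
  do_unbind <- state == 1L & u < p_off

  state[do_bind] <- 1L
  state[do_unbind] <- 0L
  bonds[cbind(lattice$m + 1L, lattice$n + 1L)] <- state
  list(bonds = bonds, n_bind = sum(do_bind), n_unbind = sum(do_unbind),
       n_clamp = n_clamp)
}

#' Bond kinetics on a frozen membrane
#'
#' Runs the Monte Carlo sweep against a fixed flat membrane at height
#' `gap`, with no membrane dynamics.  Every receptor then sees the same
#' constant bond force, so the stationary closed ratio has the closed form
#' [two_state_occupancy()]`(kon0, koff(f))` - the detailed-balance control
#' used to validate the kinetics.
#'
#' @param gap fixed membrane height (nm).
#' @param config a [sim_config()]; `k`, `h_L`, `R_RL`, rates and `dt` are
#'   used.
#' @param n_sweeps number of Monte Carlo sweeps.
#' @param bonds_init initial bond state (default all open).
#' @param sample_stride record `phi` every this many sweeps.
#' @return list: `phi` (sampled series), `time` (ns), `phi_theory` (the
#'   closed-form stationary value), `f` (bond force at the gap),
#'   `final_bonds`.
#' @export
simulate_fixed_gap <- function(gap, config, n_sweeps = 20000L,
                               bonds_init = NULL, sample_stride = 10L) {
  validate_config(config)
  Nb <- config$Nb
  n_sites <- Nb * Nb
  state <- if (is.null(bonds_init)) integer(n_sites)
           else as.integer(bonds_init)
  in_range <- abs(gap - config$h_L) <= config$R_RL
  p_on <- if (in_range) min(config$kon0 * config$dt, 1) else 0
  f <- bond_force(gap, config$k, config$h_L)
  koff <- bell_off_rate(f, config$koff0, config$x_b, config$kBT)
  p_off <- min(koff * config$dt, 1)

  set.seed(config$seed)
  n_rec <- n_sweeps %/% sample_stride
  phi <- numeric(n_rec)
  irec <- 0
  for (s in seq_len(n_sweeps)) {
    u <- stats::runif(n_sites)
    closing <- state == 0L & u < p_on
    opening <- state == 1L & u < p_off
    state[closing] <- 1L
    state[opening] <- 0L
    if (s %% sample_stride == 0) {
      irec <- irec + 1
      phi[irec] <- sum(state) / n_sites
    }
  }
  list(phi = phi, time = seq_len(n_rec) * sample_stride * config$dt,
       phi_theory = if (in_range) two_state_occupancy(config$kon0, koff) else 0,
       f = f, final_bonds = matrix(state, Nb, Nb))
}
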