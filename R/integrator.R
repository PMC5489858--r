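#' Mode-dependent hydrodynamic mobility
#'
#' Oseen-level damping of a membrane bending mode by the surrounding fluid,
#' `Lambda_q = 1 / (4 eta q)`.  The mobility diverges as `q -> 0`; the
#' centre-of-mass mode is regularised at the box scale,
#' `Lambda_0 = 1 / (4 eta q_min)` with `q_min = 2 pi / L`, and receives no
#' thermal noise (it drifts only under deterministic forces).
#'
#' @param grid a [wave_grid()].
#' @param eta viscosity (pN ns / nm^2).
#' @return real `N x N` matrix of mobilities (nm^3 / (pN ns)).
#' @export
mobility_spectrum <- function(grid, eta) {
  q <- grid$qmag
  q[1, 1] <- 2 * pi / grid$L
  1 / (4 * eta * q)
}

#' One thermal noise increment for the spectral field
#'
#' Hermitian-symmetric complex Gaussian increment with per-mode variance
#' `2 kBT L^2 Lambda_q dt` (fluctuation-dissipation for the overdamped
#' Langevin equation `dh_q/dt = Lambda_q (F_q + zeta_q)`).  Realised as the
#' DFT of an iid real white field, which guarantees the symmetry and the
#' stated variance on every mode including the self-conjugate ones.  The
#' zero mode gets no noise.  Draws from R's RNG.
#'
#' @param grid a [wave_grid()].
#' @param mobility matrix from [mobility_spectrum()].
#' @param kBT thermal energy (pN nm).
#' @param dt timestep (ns).
#' @return complex `N x N` Hermitian increment.
#' @export
noise_increment <- function(grid, mobility, kBT, dt) {
  N <- grid$N
  amp <- sqrt(2 * kBT * grid$L^2 * mobility * dt) / N
  amp[1, 1] <- 0
  w <- matrix(stats::rnorm(N * N), N, N)
  amp * stats::fft(w)
}

#' One Euler-Maruyama step of the spectral Langevin dynamics
#'
#' Advances `h_q(t + dt) = h_q(t) + dt Lambda_q F_q + xi_q`, with `xi_q`
#' from [noise_increment()] when `kBT > 0` and `noise = TRUE`.  Reference
#' implementation; production runs use [fsbd_run()] with `engine = "cpp"`.
#'
#' @param hq spectral field.
#' @param Fq deterministic force field (same convention).
#' @param grid a [wave_grid()].
#' @param config a [sim_config()] (supplies `eta`, `kBT`, `dt`).
#' @param mobility optional precomputed [mobility_spectrum()].
#' @param noise logical; draw the thermal increment?
#' @return updated spectral field.
#' @export
fsbd_step <- function(hq, Fq, grid, config, mobility = NULL, noise = TRUE) {
  if (is.null(mobility)) mobility <- mobility_spectrum(grid, config$eta)
  out <- hq + config$dt * mobility * Fq
  if (noise && config$kBT > 0)
    out <- out + noise_increment(grid, mobility, config$kBT, config$dt)
  if (!all(is.finite(Re(out)) & is.finite(Im(out)))) {
    bad <- which(!(is.finite(Re(out)) & is.finite(Im(out))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite mode amplitude at mode index (%d, %d)",
                 bad[1], bad[2]))
  }
  out
}

#' Run the coupled membrane / bond-kinetics simulation
#'
#' Integrates the spectral Langevin dynamics for `t_total / dt` steps with
#' the selected force terms, optionally running one Monte Carlo bond sweep
#' per step, and samples observables at a fixed stride.  Fully reproducible
#' given `config$seed` (one global stream: dynamics noise first, kinetics
#' second, every step).
#'
#' @param config a [sim_config()].
#' @param terms force terms, subset of
#'   `c("bending", "wall", "linkage", "pressure")`.
#' @param kinetics logical; run the bond Monte Carlo sweep each step?
#' @param noise logical; include thermal noise (set `FALSE` for
#'   zero-temperature/deterministic runs)?
#' @param hq_init optional initial spectral field; default is a flat
#'   membrane at `config$h_init`.
#' @param bonds_init optional initial bond-state matrix (default all open).
#' @param sample_stride record observables every this many steps.
#' @param spectrum_stride record `|h_q|^2` every this many steps
#'   (0 = never).
#' @param engine `"cpp"` (production) or `"r"` (pure-R reference, for small
#'   problems and cross-checks).
#' @return An object of class `"fsbd_trajectory"`: list with `samples`
#'   (data.frame: `time`, `mean_height`, `rms_height`, `phi`, `n_closed`,
#'   `E_bend`, `E_link`), `spectrum` (`N x N x n` array of `|h_q|^2`
#'   samples, or `NULL`), `final_hq`, `final_bonds`, event counts, and the
#'   `config`/`grid`/`lattice` used.
#' @export
fsbd_run <- function(config,
                     terms = c("bending", "wall", "linkage", "pressure"),
                     kinetics = TRUE, noise = TRUE,
                     hq_init = NULL, bonds_init = NULL,
                     sample_stride = 100L, spectrum_stride = 0L,
                     engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  terms <- match.arg(terms, several.ok = TRUE)
  validate_config(config)
  grid <- wave_grid(config)
  need_lattice <- kinetics || "linkage" %in% terms
  lattice <- if (need_lattice) receptor_lattice(config, grid) else NULL

  set.seed(config$seed)
  if (is.null(hq_init)) {
    hq_init <- spectral_zero(grid)
    hq_init[1, 1] <- complex(real = config$h_init * grid$L^2)
  }
  if (is.null(bonds_init)) bonds_init <- bond_state(config$Nb)
  n_steps <- as.integer(round(config$t_total / config$dt))

  if (engine == "cpp") {
    seeds <- sample.int(.Machine$integer.max, 2L)
    Nb <- if (need_lattice) config$Nb else 0L
    six <- if (need_lattice)
      matrix(lattice$ix - 1L, Nb, Nb, byrow = TRUE) else matrix(0L, 0, 0)
    siy <- if (need_lattice)
      matrix(lattice$iy - 1L, Nb, Nb, byrow = TRUE) else matrix(0L, 0, 0)
    b0 <- if (need_lattice) bonds_init else matrix(0L, 0, 0)
    res <- fsbd_run_cpp(hq_init, b0, six, siy,
                        config$L, config$dt, n_steps,
                        config$B, config$eta, config$kBT,
                        config$sigma_w, config$eps_w, config$h_sub,
                        config$k, config$h_L, config$R_RL,
                        config$kon0, config$koff0, config$x_b, config$p,
                        "bending" %in% terms, "wall" %in% terms,
                        "linkage" %in% terms, "pressure" %in% terms,
                        noise, kinetics,
                        as.integer(sample_stride), as.integer(spectrum_stride),
                        seeds[1], seeds[2])
    if (nzchar(res$error))
      stop(sprintf("integration aborted at step %d: %s",
                   res$error_step, res$error))
    samples <- data.frame(time = as.numeric(res$time),
                          mean_height = as.numeric(res$mean_height),
                          rms_height = as.numeric(res$rms_height),
                          phi = as.numeric(res$phi),
                          n_closed = as.integer(res$n_closed),
                          E_bend = as.numeric(res$E_bend),
                          E_link = as.numeric(res$E_link))
    spectrum <- if (spectrum_stride > 0 && res$n_spectrum > 0)
      res$spectrum[, , seq_len(res$n_spectrum), drop = FALSE] else NULL
    out <- list(samples = samples, spectrum = spectrum,
                final_hq = res$final_hq,
                final_bonds = if (need_lattice) res$final_bonds else NULL,
                n_bind = res$n_bind, n_unbind = res$n_unbind,
                n_clamp = res$n_clamp,
                config = config, grid = grid, lattice = lattice)
  } else {
    out <- fsbd_run_r(config, grid, lattice, terms, kinetics, noise,
                      hq_init, bonds_init, n_steps,
                      as.integer(sample_stride), as.integer(spectrum_stride))
  }
  if (out$n_clamp > 0)
    warning(sprintf("koff * dt exceeded 1 and was clamped %d time(s); ",
                    as.integer(out$n_clamp)),
            "unbinding kinetics are not resolved at this timestep")
  class(out) <- "fsbd_trajectory"
  out
}

# Pure-R reference loop; identical update order to the C++ engine but uses
# R's RNG throughout.  Intended for small N and short runs.
fsbd_run_r <- function(config, grid, lattice, terms, kinetics, noise,
                       hq, bonds, n_steps, sample_stride, spectrum_stride) {
  mobility <- mobility_spectrum(grid, config$eta)
  n_samp <- if (sample_stride > 0) n_steps %/% sample_stride else 0
  samples <- data.frame(time = numeric(n_samp), mean_height = numeric(n_samp),
                        rms_height = numeric(n_samp), phi = numeric(n_samp),
                        n_closed = integer(n_samp), E_bend = numeric(n_samp),
                        E_link = numeric(n_samp))
  n_spec <- if (spectrum_stride > 0) n_steps %/% spectrum_stride else 0
  spectrum <- if (n_spec > 0) array(0, c(grid$N, grid$N, n_spec)) else NULL
  isamp <- 0; ispec <- 0
  n_bind <- 0; n_unbind <- 0; n_clamp <- 0
  for (step in seq_len(n_steps)) {
    h <- to_real(hq, grid, on_asymmetry = "ignore")
    Fq <- total_force(hq, h, bonds, config, grid, lattice, terms)
    hq <- fsbd_step(hq, Fq, grid, config, mobility, noise)
    if (kinetics && !is.null(lattice)) {
      h <- to_real(hq, grid, on_asymmetry = "ignore")
      sw <- kinetic_sweep(bonds, h, config, lattice)
      bonds <- sw$bonds
      n_bind <- n_bind + sw$n_bind
      n_unbind <- n_unbind + sw$n_unbind
      n_clamp <- n_clamp + sw$n_clamp
    }
    if (sample_stride > 0 && step %% sample_stride == 0) {
      h <- to_real(hq, grid, on_asymmetry = "ignore")
      isamp <- isamp + 1
      nc <- if (!is.null(lattice)) sum(bonds) else 0L
      samples[isamp, ] <- list(
        step * config$dt, mean(h), sqrt(mean(h^2)),
        if (!is.null(lattice)) nc / config$Nb^2 else NA_real_, nc,
        bending_energy(hq, grid, config$B),
        if (!is.null(lattice))
          linkage_energy(h, bonds, config$k, config$h_L, lattice) else 0)
    }
    if (spectrum_stride > 0 && step %% spectrum_stride == 0) {
      ispec <- ispec + 1
      spectrum[, , ispec] <- Mod(hq)^2
    }
  }
  list(samples = samples, spectrum = spectrum, final_hq = hq,
       final_bonds = if (!is.null(lattice)) bonds else NULL,
       n_bind = n_bind, n_unbind = n_unbind, n_clamp = n_clamp,
       config = config, grid = grid, lattice = lattice)
}

#' @export
print.fsbd_trajectory <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<fsbd_trajectory> %d samples over %g ns\n",
              n, if (n) max(x$samples$time) else 0))
  if (n) {
    last <- x$samples[n, ]
    cat(sprintf("  final: mean height %.3g nm, rms %.3g nm, phi %.3g\n",
                last$mean_height, last$rms_height, last$phi))
  }
  invisible(x)
}
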