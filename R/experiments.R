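#' Preset: free-membrane validation run
#'
#' Parameters of the free-membrane spectrum validation: `B = 20` pN nm
#' (about 5 kBT), `kBT = 4.3` pN nm, `eta = 0.06` Poise,
#' `lambda_min = 20` nm.  `scale = "paper"` uses the full `L = 800` nm box,
#' `dt = 0.5` ns and 1 ms of simulated time; `scale = "quick"` uses a
#' 240 nm box for 1 ms at `dt = 0.05` ns.  The finer quick-preset timestep
#' is an accuracy choice: the Euler scheme inflates each mode's stationary
#' variance by about `dt / (2 tau_q)`, and the long average resolves the
#' spectrum to a few tenths of a percent, so the fastest modes
#' (`tau = 14-40` ns) need `dt` well below half a nanosecond for the bias
#' to stay below the statistical resolution.
#'
#' @param scale `"quick"` or `"paper"`.
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
free_membrane_config <- function(scale = c("quick", "paper"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "paper")
    sim_config(L = 800, alpha_max = 40L, B = 20, eta = poise(0.06),
               kBT = 4.3, dt = 0.5, t_total = 1e6, seed = seed,
               p = 0, h_init = 0, kon0 = 0, koff0 = 0)
  else
    sim_config(L = 240, alpha_max = 12L, B = 20, eta = poise(0.06),
               kBT = 4.3, dt = 0.05, t_total = 1e6, seed = seed,
               Delta = 20, p = 0, h_init = 0, kon0 = 0, koff0 = 0)
}

#' Free-membrane spectrum experiment
#'
#' Integrates the membrane under bending forces alone and compares the
#' radially binned fluctuation spectrum with the equipartition prediction
#' `<|h_q|^2> = kBT L^2 / (B q^4)`, and the spatial RMS height with both
#' the continuum estimate [rms_height_analytic()] and the exact mode sum
#' [rms_height_modes()].  The run starts from an equilibrium spectrum draw
#' (see [equilibrium_spectrum()]) so all sampling happens in stationarity;
#' set `equilibrium_init = FALSE` to start flat and watch the transient.
#'
#' @param config a [sim_config()]; default [free_membrane_config()].
#' @param spectrum_stride,sample_stride sampling strides (steps).
#' @param equilibrium_init start from the stationary ensemble?
#' @param discard_frac burn-in fraction discarded by the estimators.
#' @return list: `spectrum` (data.frame from [fluctuation_spectrum()]),
#'   `rms_sim`, `rms_se`, `rms_analytic`, `rms_modes`, `ratio`
#'   (simulated / analytic), and the `trajectory`.
#' @export
run_free_membrane <- function(config = free_membrane_config(),
                              spectrum_stride = NULL, sample_stride = NULL,
                              equilibrium_init = TRUE, discard_frac = 0.2) {
  # default sampling: spectrum every ~100 ns, scalars every ~50 ns
  if (is.null(spectrum_stride))
    spectrum_stride <- max(1L, as.integer(round(100 / config$dt)))
  if (is.null(sample_stride))
    sample_stride <- max(1L, as.integer(round(50 / config$dt)))
  grid <- wave_grid(config)
  hq0 <- NULL
  if (equilibrium_init && config$kBT > 0) {
    set.seed(config$seed + 1013904L)
    hq0 <- equilibrium_spectrum(grid, config$B, config$kBT, h0 = config$h_init)
  }
  traj <- fsbd_run(config, terms = "bending", kinetics = FALSE,
                   hq_init = hq0, sample_stride = sample_stride,
                   spectrum_stride = spectrum_stride)
  spec <- if (spectrum_stride > 0)
    fluctuation_spectrum(traj, discard_frac = discard_frac) else NULL
  keep <- seq.int(floor(discard_frac * nrow(traj$samples)) + 1L,
                  nrow(traj$samples))
  rms2 <- block_se(traj$samples$rms_height[keep]^2, 10L)
  rms_sim <- sqrt(rms2$mean)
  rms_an <- rms_height_analytic(config$L, config$B, config$kBT)
  list(spectrum = spec,
       rms_sim = rms_sim,
       rms_se = rms2$se / (2 * rms_sim),
       rms_analytic = rms_an,
       rms_modes = rms_height_modes(config$L, config$B, config$kBT,
                                    config$alpha_max),
       ratio = rms_sim / rms_an,
       trajectory = traj)
}

#' Preset: entropic-pressure sweep base configuration
#'
#' Hard-wall regime for measuring the Helfrich repulsion coefficient:
#' `L = 240` nm (the pressure-distance relation is insensitive to box size
#' at fixed `lambda_min`), `lambda_min = 20` nm, small wall length
#' `sigma_w = 2` nm, `eps_w = 0.043` pN/nm, `dt = 0.25` ns (halved relative
#' to the free run: the ninth-power wall is much stiffer than the bending
#' force at contact), 0.3 ms per pressure.
#'
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
entropic_config <- function(seed = 1L) {
  sim_config(L = 240, alpha_max = 12L, B = 20, eta = poise(0.06), kBT = 4.3,
             dt = 0.25, t_total = 3e5, seed = seed,
             sigma_w = 2, eps_w = 0.043, h_sub = 0, Delta = 20,
             kon0 = 0, koff0 = 0)
}

#' Entropic pressure-distance sweep
#'
#' For each applied pressure `p`, integrates the membrane under bending +
#' soft wall + uniform pressure until the mean gap `d` equilibrates, then
#' fits the Helfrich law `p = c (kBT)^2 / (B d^3)` with the exponent fixed
#' at -3 (see [fit_entropic_coefficient()]).  Each run starts from a flat
#' membrane at the gap the law itself predicts for `c = 0.1` (a starting
#' guess only; burn-in is discarded) and is flagged if the retained segment
#' still drifts.
#'
#' @param pressures applied pressures (pN/nm^2), at least 3.
#' @param config base [sim_config()]; default [entropic_config()].
#' @param sample_stride sampling stride (steps).
#' @param discard_frac burn-in fraction.
#' @return list: `curve` (data.frame `p`, `d`, `se`, `d_theory`, `drift`),
#'   `c_fit`, and `config`.
#' @export
run_entropic_pressure_sweep <- function(pressures = c(1, 2, 4, 8, 16) * 1e-4,
                                        config = entropic_config(),
                                        sample_stride = 100L,
                                        discard_frac = 0.2) {
  stopifnot(length(pressures) >= 3, all(pressures > 0))
  rows <- lapply(seq_along(pressures), function(i) {
    p <- pressures[i]
    d0 <- (0.1 * config$kBT^2 / (config$B * p))^(1 / 3)
    cfg <- update_config(config, p = p, h_init = d0 + config$h_sub,
                         seed = config$seed + 7L * i)
    traj <- fsbd_run(cfg, terms = c("bending", "wall", "pressure"),
                     kinetics = FALSE, sample_stride = sample_stride)
    g <- mean_gap(traj, discard_frac = discard_frac)
    x <- traj$samples$mean_height
    keep <- seq.int(floor(discard_frac * length(x)) + 1L, length(x))
    half <- length(keep) %/% 2
    a <- block_se(x[keep[seq_len(half)]], 10L)
    b <- block_se(x[keep[-seq_len(half)]], 10L)
    drift <- abs(a$mean - b$mean) > 3 * sqrt(a$se^2 + b$se^2)
    data.frame(p = p, d = g$d, se = g$se, drift = drift)
  })
  curve <- do.call(rbind, rows)
  c_fit <- fit_entropic_coefficient(curve, config$B, config$kBT)
  curve$d_theory <- (c_fit * config$kBT^2 / (config$B * curve$p))^(1 / 3)
  list(curve = curve, c_fit = c_fit, config = config)
}

#' Preset: adhesion (FSBD-MC) base configuration
#'
#' Coupled membrane / bond-kinetics runs: weak holding pressure
#' `p = 4e-5` pN/nm^2 (prevents the membrane from diffusing away from the
#' substrate), `h_L = -1.2` nm, `sigma_w = 4` nm, `eps_w = 0.043` pN/nm
#' (0.01 kBT/nm^2), receptor spacing `Delta = 10` nm on a 240 nm box,
#' intrinsic rates at their physiological upper bounds `kon0 = 1` /ns and
#' `koff0 = 1e-4` /ns (equilibrium constant `1e4`, i.e. a 10 kBT binding
#' energy), Bell length `x_b = 0.5` nm, encounter distance `R_RL = 2` nm,
#' `dt = 0.25` ns, 0.2 ms per run.  `R_RL` and `x_b` are free parameters
#' of the model (no measured values exist for a lumped linkage); these
#' defaults put the scaled 240 nm box in the smoothly adhered regime - see
#' the methods vignette for the calibration rationale and for the abrupt
#' detachment the small box shows outside it.
#'
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
adhesion_config <- function(seed = 1L) {
  sim_config(L = 240, alpha_max = 12L, B = 20, eta = poise(0.06), kBT = 4.3,
             dt = 0.25, t_total = 2e5, seed = seed,
             sigma_w = 4, eps_w = 0.043, h_sub = 0,
             k = 10, h_L = -1.2, Delta = 10,
             R_RL = 2, kon0 = 1, koff0 = 1e-4, x_b = 0.5, p = 4e-5)
}

#' Substrate-stiffness sweep of the closed bond ratio
#'
#' Runs the full coupled simulation for each linkage stiffness `k` and
#' reports the equilibrium closed bond ratio `phi` and mean gap `d`.
#' Because the lumped linkage spring stands in for the substrate Young's
#' modulus, the `phi(k)` curve is the substrate-rigidity dependence of
#' adhesion; with rates at their upper bounds it rises (stiffer substrate
#' pins the membrane closer, raising rebinding) and then falls (stiffer
#' springs transmit larger Bell forces, raising unbinding).
#'
#' @param k_values linkage stiffnesses (pN/nm), spanning >= 2 decades.
#' @param config base [sim_config()]; default [adhesion_config()].
#' @param rate_scale multiplies both `kon0` and `koff0` (e.g. 0.01 for the
#'   reduced-rate comparison).
#' @param adhered_start start each run fully adhered (all bonds closed,
#'   membrane flat at `h_L`)?  Default `TRUE`: the sweeps measure the
#'   equilibrium of the adhered state, and at slow intrinsic rates
#'   nucleation from a detached start is itself a slow process that would
#'   otherwise dominate the run.  At the fast default rates the steady
#'   state is the same from either start.
#' @param sample_stride sampling stride (steps).
#' @param discard_frac burn-in fraction.
#' @return list: `table` (data.frame `k`, `phi`, `se`, `d`, `d_se`),
#'   `k_max` (the stiffness with maximal `phi`), and `config`.
#' @export
run_stiffness_sweep <- function(k_values = c(0.3, 1, 3, 10, 30),
                                config = adhesion_config(),
                                rate_scale = 1, adhered_start = TRUE,
                                sample_stride = 100L, discard_frac = 0.2) {
  stopifnot(length(k_values) >= 2, all(k_values > 0))
  rows <- lapply(seq_along(k_values), function(i) {
    cfg <- update_config(config, k = k_values[i],
                         kon0 = config$kon0 * rate_scale,
                         koff0 = config$koff0 * rate_scale,
                         h_init = if (adhered_start) config$h_L
                                  else config$h_init,
                         seed = config$seed + 11L * i)
    b0 <- if (adhered_start) bond_state(cfg$Nb, closed = TRUE) else NULL
    traj <- fsbd_run(cfg, kinetics = TRUE, bonds_init = b0,
                     sample_stride = sample_stride)
    ph <- closed_bond_ratio_series(traj, discard_frac = discard_frac)
    g <- mean_gap(traj, discard_frac = discard_frac)
    data.frame(k = k_values[i], phi = ph$phi, se = ph$se,
               d = g$d, d_se = g$se)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, k_max = tab$k[which.max(tab$phi)], config = config)
}

#' Receptor-density sweep of the closed bond ratio
#'
#' Runs the full coupled simulation for each receptor spacing `Delta`
#' (density `1 / Delta^2`); the closed bond ratio decreases monotonically
#' as receptors get sparser, because fewer pinning sites leave the membrane
#' further from the substrate under the entropic repulsion.
#'
#' @param Delta_values receptor spacings (nm), each a multiple of the grid
#'   spacing.
#' @param config base [sim_config()]; default [adhesion_config()].
#' @param adhered_start start each run fully adhered (see
#'   [run_stiffness_sweep()]).
#' @param sample_stride sampling stride (steps).
#' @param discard_frac burn-in fraction.
#' @return list: `table` (data.frame `Delta`, `Nb`, `phi`, `se`, `d`,
#'   `d_se`) and `config`.
#' @export
run_density_sweep <- function(Delta_values = c(10, 20, 30, 40),
                              config = adhesion_config(),
                              adhered_start = TRUE,
                              sample_stride = 100L, discard_frac = 0.2) {
  stopifnot(length(Delta_values) >= 2, all(Delta_values > 0))
  rows <- lapply(seq_along(Delta_values), function(i) {
    cfg <- update_config(config, Delta = Delta_values[i],
                         h_init = if (adhered_start) config$h_L
                                  else config$h_init,
                         seed = config$seed + 13L * i)
    b0 <- if (adhered_start) bond_state(cfg$Nb, closed = TRUE) else NULL
    traj <- fsbd_run(cfg, kinetics = TRUE, bonds_init = b0,
                     sample_stride = sample_stride)
    ph <- closed_bond_ratio_series(traj, discard_frac = discard_frac)
    g <- mean_gap(traj, discard_frac = discard_frac)
    data.frame(Delta = Delta_values[i], Nb = cfg$Nb, phi = ph$phi,
               se = ph$se, d = g$d, d_se = g$se)
  })
  list(table = do.call(rbind, rows), config = config)
}

#' Write a table as TSV with the full parameter set as header comments
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config a [sim_config()] echoed into `# key = value` comment
#'   lines (provenance).
#' @param extra optional named list of extra comment fields.
#' @return `path`, invisibly.
#' @export
write_table_commented <- function(df, path, config = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    flds <- unclass(config)
    for (nm in names(flds))
      writeLines(sprintf("# %s = %s", nm, format(flds[[nm]])), con)
  }
  if (!is.null(extra))
    for (nm in names(extra))
      writeLines(sprintf("# %s = %s", nm, format(extra[[nm]])), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
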