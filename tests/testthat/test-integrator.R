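test_that("mobility spectrum is 1/(4 eta q) with a regularised zero mode", {
  g <- wave_grid(80, 4)
  eta <- 6
  lam <- mobility_spectrum(g, eta)
  expect_equal(lam[2, 1], 1 / (4 * eta * 2 * pi / 80))
  expect_equal(lam[1, 1], 1 / (4 * eta * 2 * pi / 80))  # box-scale cap
  expect_true(all(lam > 0))
})

test_that("noise increments are Hermitian with the fluctuation-dissipation variance", {
  g <- wave_grid(80, 4)
  lam <- mobility_spectrum(g, 6)
  kBT <- 4.3; dt <- 0.5
  set.seed(21)
  n <- 4000
  acc <- matrix(0, g$N, g$N)
  for (i in seq_len(n)) {
    xi <- noise_increment(g, lam, kBT, dt)
    expect_true(is_hermitian_field(xi, tol = 1e-8))
    acc <- acc + Mod(xi)^2
  }
  target <- 2 * kBT * g$L^2 * lam * dt
  target[1, 1] <- 0
  ratio <- (acc / n)[-1] / target[-1]
  # per-mode chi^2 averaging: se of the ratio ~ sqrt(2/n) (pairs) or 2/n
  expect_true(all(abs(ratio - 1) < 6 * sqrt(2 / n)))
  expect_equal(acc[1, 1], 0)
})

test_that("state is unchanged without forces at zero temperature", {
  g <- wave_grid(80, 4)
  cfg <- tiny_config(kBT = 0)
  hq <- random_hermitian(g)
  out <- fsbd_step(hq, spectral_zero(g), g, cfg)
  expect_identical(out, hq)
})

test_that("zero-temperature single-mode decay follows the closed form", {
  cfg <- tiny_config(kBT = 0, dt = 0.2, B = 20, eta = 6)
  g <- wave_grid(cfg)
  lam <- mobility_spectrum(g, cfg$eta)
  a0 <- 50
  hq <- spectral_zero(g)
  hq[2, 1] <- a0; hq[g$N, 1] <- a0  # conjugate pair, lambda = L
  q0 <- g$qmag[2, 1]
  n <- 200
  for (i in seq_len(n))
    hq <- fsbd_step(hq, bending_force(hq, g, cfg$B), g, cfg, lam,
                    noise = FALSE)
  decay <- (1 - cfg$dt * lam[2, 1] * cfg$B * q0^4)^n
  expect_equal(Re(hq[2, 1]), a0 * decay, tolerance = 1e-12)
  # matches exp(-t/tau) with tau = 4 eta / (B q^3) up to O(dt)
  tau <- mode_relaxation_time(g$L, cfg$B, cfg$eta)
  expect_equal(tau, 4 * cfg$eta / (cfg$B * q0^3), tolerance = 1e-12)
  t_n <- n * cfg$dt
  rel_err <- abs(Re(hq[2, 1]) - a0 * exp(-t_n / tau)) / (a0 * exp(-t_n / tau))
  expect_lt(rel_err, cfg$dt / tau)  # discretization error O(dt/tau) per decade
})

test_that("cpp and R engines agree exactly on deterministic runs", {
  cfg <- tiny_config(kBT = 0, t_total = 25, dt = 0.5, p = 1e-3, k = 5,
                     h_L = -1.2, kon0 = 0, koff0 = 0)
  g <- wave_grid(cfg)
  set.seed(31)
  hq0 <- random_hermitian(g, scale = 4)
  hq0[1, 1] <- 2 * g$L^2  # start above the wall plane, mean height 2 nm
  b0 <- bond_state(cfg$Nb); b0[1, 1] <- 1L; b0[2, 2] <- 1L
  args <- list(config = cfg, kinetics = FALSE, noise = FALSE,
               hq_init = hq0, bonds_init = b0, sample_stride = 10L)
  t_cpp <- do.call(fsbd_run, c(args, engine = "cpp"))
  t_r <- do.call(fsbd_run, c(args, engine = "r"))
  expect_equal(t_cpp$final_hq, t_r$final_hq, tolerance = 1e-10)
  expect_equal(t_cpp$samples$mean_height, t_r$samples$mean_height,
               tolerance = 1e-10)
  expect_equal(t_cpp$samples$E_bend, t_r$samples$E_bend, tolerance = 1e-8)
  expect_equal(t_cpp$samples$E_link, t_r$samples$E_link, tolerance = 1e-8)
})

test_that("trajectories are reproducible given the seed", {
  cfg <- tiny_config(kBT = 4.3, t_total = 200, seed = 77,
                     kon0 = 0.1, koff0 = 1e-3, dt = 0.5)
  a <- fsbd_run(cfg, kinetics = TRUE, sample_stride = 20L)
  b <- fsbd_run(cfg, kinetics = TRUE, sample_stride = 20L)
  expect_identical(a$samples, b$samples)
  expect_identical(a$final_hq, b$final_hq)
  expect_identical(a$final_bonds, b$final_bonds)
  c2 <- fsbd_run(update_config(cfg, seed = 78), kinetics = TRUE,
                 sample_stride = 20L)
  expect_false(identical(a$samples$rms_height, c2$samples$rms_height))
})

test_that("thermal free membrane reaches equipartition mode variances", {
  # small box so every mode relaxes quickly: tau_max = 2.5 us, run 100 us
  cfg <- tiny_config(L = 80, alpha_max = 4L, kBT = 4.3, B = 20, eta = 6,
                     dt = 0.5, t_total = 1e5, seed = 5, kon0 = 0, koff0 = 0)
  g <- wave_grid(cfg)
  traj <- fsbd_run(cfg, terms = "bending", kinetics = FALSE,
                   sample_stride = 50L, spectrum_stride = 50L)
  expect_true(is_hermitian_field(traj$final_hq, tol = 1e-8))
  spec <- fluctuation_spectrum(traj, discard_frac = 0.3, n_blocks = 10L)
  z <- (spec$power - spec$theory) / spec$se
  expect_true(all(abs(z) < 4))
  # spatial RMS agrees with the discrete-mode equipartition sum
  keep <- seq(floor(0.3 * nrow(traj$samples)), nrow(traj$samples))
  rms_sim <- sqrt(mean(traj$samples$rms_height[keep]^2))
  expect_equal(rms_sim,
               rms_height_modes(cfg$L, cfg$B, cfg$kBT, cfg$alpha_max),
               tolerance = 0.1)
})

test_that("integration aborts with a diagnostic on non-finite amplitudes", {
  cfg <- tiny_config(kBT = 0, dt = 1e9, t_total = 2e10, p = 10,
                     sigma_w = 1, kon0 = 0)  # wildly unstable on purpose
  expect_error(
    fsbd_run(cfg, terms = c("bending", "wall", "pressure"), kinetics = FALSE,
             hq_init = {
               g <- wave_grid(cfg)
               hq <- spectral_zero(g); hq[1, 1] <- 5 * g$L^2; hq
             },
             sample_stride = 1L),
    "aborted|singularity|non-finite")
})
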