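test_that("analytic free-membrane amplitudes have the right limits and scalings", {
  expect_equal(rms_height_analytic(800, 20, 4.3),
               sqrt(800^2 * 4.3 / (4 * pi^3 * 20)))
  expect_equal(rms_height_analytic(800, 1e12, 4.3), 0, tolerance = 1e-3)
  # doubling L doubles the RMS; quadrupling B halves it
  expect_equal(rms_height_analytic(1600, 20, 4.3),
               2 * rms_height_analytic(800, 20, 4.3))
  expect_equal(rms_height_analytic(800, 80, 4.3),
               rms_height_analytic(800, 20, 4.3) / 2)
  expect_equal(relative_amplitude(20, 4.3),
               rms_height_analytic(800, 20, 4.3) / 800)
  # the discrete-mode sum is below the continuum estimate at these cutoffs
  expect_lt(rms_height_modes(800, 20, 4.3, 40),
            rms_height_analytic(800, 20, 4.3))
})

test_that("mode relaxation time scales as eta lambda^3 / B", {
  tau <- mode_relaxation_time(20, 20, 6)
  expect_equal(tau, 4 * 6 * 20^3 / (20 * (2 * pi)^3))
  expect_equal(mode_relaxation_time(40, 20, 6), 8 * tau)
  expect_equal(mode_relaxation_time(20, 40, 6), tau / 2)
  expect_equal(mode_relaxation_time(20, 20, 12), 2 * tau)
})

test_that("block averaging reports mean and a sane standard error", {
  x <- rep(c(1, 3), 50)
  bs <- block_se(x, n_blocks = 10L)
  expect_equal(bs$mean, 2)
  expect_equal(bs$se, 0)
  set.seed(13)
  y <- rnorm(2000)
  bs <- block_se(y, n_blocks = 20L)
  expect_equal(bs$mean, mean(y[1:2000]), tolerance = 1e-12)
  expect_gt(bs$se, 0)
  expect_lt(bs$se, 0.1)
  expect_error(block_se(1:3, n_blocks = 10L), NA)  # clamps blocks, no error
})

test_that("spectrum of a frozen field is the field's own power", {
  g <- wave_grid(80, 4)
  set.seed(17)
  hq <- random_hermitian(g, scale = 5)
  pw <- Mod(hq)^2
  arr <- array(rep(pw, 120), c(g$N, g$N, 120))
  spec <- fluctuation_spectrum(arr, grid = g, B = 20, kBT = 4.3,
                               discard_frac = 0, n_blocks = 5L)
  # reconstruct per-bin means of the frozen power independently
  dq <- 2 * pi / g$L
  bin <- round(g$qmag / dq); bin[1, 1] <- -1
  for (i in seq_len(nrow(spec))) {
    sel <- bin == round(spec$q[i] / dq)
    expect_equal(spec$power[i], mean(pw[sel]), tolerance = 1e-12)
  }
  expect_true(all(spec$se < 1e-12))
  expect_error(fluctuation_spectrum(arr[, , 1:50], grid = g, B = 20,
                                    kBT = 4.3, discard_frac = 0),
               "at least 100")
})

test_that("mean gap averages the equilibrated mean height above the wall", {
  tr <- fake_traj(rep(5, 100), h_sub = 0)
  g <- mean_gap(tr, discard_frac = 0.2)
  expect_equal(g$d, 5)
  expect_equal(g$se, 0)
  tr2 <- fake_traj(c(rep(100, 50), rep(5, 50)))  # burn-in is discarded
  expect_equal(mean_gap(tr2, discard_frac = 0.5)$d, 5)
  expect_warning(mean_gap(fake_traj(rep(-1, 50))), "negative mean gap")
})

test_that("closed bond ratio series averages phi with block errors", {
  tr <- fake_traj(rep(0, 80), phi = rep(1, 80))
  est <- closed_bond_ratio_series(tr)
  expect_equal(est$phi, 1)
  expect_equal(est$se, 0)
  expect_error(closed_bond_ratio_series(fake_traj(rep(0, 10))), "NA")
  # kon0 = 0 from an all-open start stays at zero occupancy
  cfg <- tiny_config(Delta = 20, kon0 = 0, koff0 = 1e-3, dt = 0.5)
  res <- simulate_fixed_gap(cfg$h_L, cfg, n_sweeps = 2000L)
  expect_equal(closed_bond_ratio_series(res$phi)$phi, 0)
})

test_that("entropic coefficient fit inverts the pressure law exactly", {
  B <- 20; kBT <- 4.3; c_true <- 0.078
  d <- c(3, 4.5, 6, 9, 12)
  curve <- data.frame(p = entropic_pressure(d, B, kBT, c_true), d = d)
  expect_equal(fit_entropic_coefficient(curve, B, kBT), c_true,
               tolerance = 1e-12)
  expect_error(fit_entropic_coefficient(curve[1:2, ], B, kBT), "at least 3")
  bad <- curve; bad$d <- rev(bad$d)
  expect_error(fit_entropic_coefficient(bad, B, kBT), "not monotone")
})

test_that("entropic coefficient fit is robust to measurement noise", {
  B <- 20; kBT <- 4.3; c_true <- 0.078
  d <- c(3, 4.5, 6, 9, 12)
  p <- entropic_pressure(d, B, kBT, c_true)
  set.seed(19)
  fits <- replicate(100, {
    dn <- d * (1 + rnorm(length(d), sd = 0.05))
    cv <- data.frame(p = p, d = sort(dn))  # keep pairing monotone like the truth
    fit_entropic_coefficient(cv, B, kBT)
  })
  expect_true(all(abs(fits / c_true - 1) < 0.5))
  expect_lt(abs(mean(fits) / c_true - 1), 0.1)
})
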