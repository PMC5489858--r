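# spectral inner product <P, dh> = L^-2 Re sum_q F_q Conj(dh_q); used by the
# energy-consistency oracle E(h + e dh) - E(h) = -e <P, dh> + O(e^2)
spectral_inner <- function(Fq, dhq, grid) {
  Re(sum(Fq * Conj(dhq))) / grid$L^2
}

test_that("bending force is -B q^4 h_q and consistent with the bending energy", {
  g <- wave_grid(80, 4)
  B <- 20
  expect_equal(bending_force(spectral_zero(g), g, B), spectral_zero(g))

  hq <- spectral_zero(g)
  hq[2, 3] <- 5 + 2i
  hq[g$N, g$N - 1] <- Conj(hq[2, 3])
  q0 <- g$qmag[2, 3]
  Fq <- bending_force(hq, g, B)
  expect_equal(Fq[2, 3], -B * q0^4 * (5 + 2i))
  expect_equal(Fq[1, 1], 0 + 0i)  # zero mode feels no bending force

  # energy gradient: numerical directional derivative of E_b
  set.seed(3)
  hq <- random_hermitian(g, scale = 10)
  dhq <- random_hermitian(g)
  eps <- 1e-6
  dE <- bending_energy(hq + eps * dhq, g, B) - bending_energy(hq, g, B)
  expect_equal(dE / eps, -spectral_inner(bending_force(hq, g, B), dhq, g),
               tolerance = 1e-4)
})

test_that("linkage force handles open, relaxed and loaded bonds", {
  cfg <- tiny_config(k = 5, h_L = -1.2, Delta = 20, kon0 = 0)
  g <- wave_grid(cfg)
  lat <- receptor_lattice(cfg, g)
  h <- matrix(1.5, g$N, g$N)

  # all open -> zero force
  expect_equal(linkage_force(h, bond_state(cfg$Nb), cfg$k, cfg$h_L, lat, g),
               spectral_zero(g))

  # one closed bond at zero extension -> zero force
  b <- bond_state(cfg$Nb)
  b[1, 1] <- 1L
  h0 <- h; h0[1, 1] <- cfg$h_L
  expect_equal(linkage_force(h0, b, cfg$k, cfg$h_L, lat, g),
               spectral_zero(g))

  # one closed bond at the origin with extension e: flat spectrum -k e
  e <- h[1, 1] - cfg$h_L
  Fq <- linkage_force(h, b, cfg$k, cfg$h_L, lat, g)
  expect_equal(Fq, matrix(complex(real = -cfg$k * e), g$N, g$N),
               tolerance = 1e-12)
})

test_that("linkage force matches direct summation over closed bonds", {
  cfg <- tiny_config(k = 3, h_L = 0.5, Delta = 20, kon0 = 0)
  g <- wave_grid(cfg)
  lat <- receptor_lattice(cfg, g)
  set.seed(5)
  h <- matrix(rnorm(g$N^2, sd = 2), g$N, g$N)
  b <- matrix(rbinom(cfg$Nb^2, 1, 0.5), cfg$Nb, cfg$Nb)

  Fq <- linkage_force(h, b, cfg$k, cfg$h_L, lat, g)
  # oracle: F_q = -sum_mn phi_mn k (h(x_mn) - h_L) exp(-i q.x_mn)
  Fref <- spectral_zero(g)
  for (r in seq_len(nrow(lat))) {
    if (b[lat$m[r] + 1, lat$n[r] + 1] == 1) {
      ext <- h[lat$ix[r], lat$iy[r]] - cfg$h_L
      Fref <- Fref - cfg$k * ext *
        exp(-1i * (g$qx * lat$x[r] + g$qy * lat$y[r]))
    }
  }
  expect_equal(Fq, Fref, tolerance = 1e-10)

  # energy consistency against linkage_energy
  hq <- to_fourier(h, g)
  dhq <- random_hermitian(g)
  dh <- to_real(dhq, g)
  eps <- 1e-6
  dE <- linkage_energy(h + eps * dh, b, cfg$k, cfg$h_L, lat) -
        linkage_energy(h, b, cfg$k, cfg$h_L, lat)
  expect_equal(dE / eps, -Re(sum(Fq * Conj(dhq))) / g$L^2, tolerance = 1e-4)
})

test_that("soft wall pressure follows the truncated ninth-power law", {
  sw <- 4; ew <- 0.043
  # above the truncation height: inactive
  expect_equal(wall_pressure(1, sw, ew), 0)
  # at the truncation height: 8 eps_w / sigma_w
  expect_equal(wall_pressure(0, sw, ew), 8 * ew / sw)
  # 2 nm into the wall: 8 (eps/sigma) (sigma / (sigma - 2))^9 = 44.032
  expect_equal(wall_pressure(-2, sw, ew), 8 * (0.043 / 4) * 2^9)
  expect_equal(wall_pressure(-2, sw, ew), 44.032, tolerance = 1e-12)
  # repulsion is never negative
  expect_true(all(wall_pressure(seq(-3.9, 5, by = 0.1), sw, ew) >= 0))
  # singularity
  expect_error(wall_pressure(-4, sw, ew), "singularity")
})

test_that("wall force transforms the pointwise pressure", {
  g <- wave_grid(80, 4)
  # fully above the wall: zero force
  expect_equal(wall_force(matrix(1, g$N, g$N), g, 2, 0.043),
               spectral_zero(g))
  # uniform contact at h = h_sub: only the zero mode, F_0 = L^2 8 eps/sigma
  Fq <- wall_force(matrix(0, g$N, g$N), g, 2, 0.043)
  expect_equal(Re(Fq[1, 1]), g$L^2 * 8 * 0.043 / 2, tolerance = 1e-10)
  expect_lt(max(Mod(Fq[-1])), 1e-8)
})

test_that("uniform pressure acts on the zero mode only", {
  g <- wave_grid(800, 40)
  expect_equal(pressure_force(0, g), spectral_zero(g))
  Fq <- pressure_force(4e-5, g)
  expect_equal(Re(Fq[1, 1]), -25.6)
  expect_equal(sum(Mod(Fq) > 0), 1L)
})

test_that("total force is the sum of its enabled terms and stays Hermitian", {
  cfg <- tiny_config(k = 5, p = 2e-4, kon0 = 0)
  g <- wave_grid(cfg)
  lat <- receptor_lattice(cfg, g)
  set.seed(9)
  hq <- random_hermitian(g, scale = 3)
  h <- to_real(hq, g) - 1  # partially in the wall
  hq <- to_fourier(h, g)
  b <- matrix(rbinom(cfg$Nb^2, 1, 0.5), cfg$Nb, cfg$Nb)

  Ftot <- total_force(hq, h, b, cfg, g, lat)
  Fsum <- bending_force(hq, g, cfg$B) +
    wall_force(h, g, cfg$sigma_w, cfg$eps_w, cfg$h_sub) +
    linkage_force(h, b, cfg$k, cfg$h_L, lat, g) +
    pressure_force(cfg$p, g)
  expect_equal(Ftot, Fsum, tolerance = 1e-12)
  expect_true(is_hermitian_field(Ftot))

  # free-membrane mode: bending only
  expect_equal(total_force(hq, h, NULL, cfg, g, NULL, terms = "bending"),
               bending_force(hq, g, cfg$B))
  expect_error(total_force(hq, h, NULL, cfg, g, NULL,
                           terms = c("bending", "linkage")),
               "requires bonds")
})
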