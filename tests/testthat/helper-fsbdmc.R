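# Small configurations used across tests.  An 80 nm box with alpha_max = 4
# (N = 8) keeps direct-summation oracles and short dynamics runs cheap.

tiny_config <- function(...) {
  defaults <- list(L = 80, alpha_max = 4L, B = 20, eta = 6, kBT = 4.3,
                   dt = 0.5, t_total = 100, seed = 42L,
                   sigma_w = 2, eps_w = 0.043, h_sub = 0,
                   k = 5, h_L = -1.2, Delta = 20, R_RL = 1,
                   kon0 = 0, koff0 = 0, x_b = 1, p = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# random Hermitian-symmetric spectral field with band-limited support
random_hermitian <- function(grid, scale = 1) {
  N <- grid$N
  w <- matrix(stats::rnorm(N * N), N, N)
  stats::fft(w) * scale / N
}

# direct O(N^4) evaluation of h_q = (L/N)^2 sum_x h(x) exp(-i q.x);
# independent of the fft-based implementation under test
dft_direct <- function(h, grid) {
  N <- grid$N
  out <- matrix(complex(real = 0), N, N)
  xs <- (seq_len(N) - 1) * grid$dx
  for (qi in seq_len(N)) {
    for (qj in seq_len(N)) {
      qx <- grid$qx[qi, qj]
      qy <- grid$qy[qi, qj]
      ph <- exp(-1i * (outer(xs * qx, xs * qy, "+")))
      out[qi, qj] <- sum(h * ph) * grid$dx^2
    }
  }
  out
}

# minimal trajectory-shaped object for observable estimators
fake_traj <- function(mean_height, phi = NULL, h_sub = 0) {
  structure(list(samples = data.frame(
    time = seq_along(mean_height),
    mean_height = mean_height,
    rms_height = abs(mean_height),
    phi = if (is.null(phi)) NA_real_ else phi,
    n_closed = 0L, E_bend = 0, E_link = 0),
    config = list(h_sub = h_sub)),
    class = "fsbd_trajectory")
}
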