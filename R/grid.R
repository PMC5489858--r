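#' Wavevector grid for the spectral membrane representation
#'
#' Builds the standard 2-D DFT mode set for an `L` x `L` periodic box with
#' `N = 2 * alpha_max` collocation points per side.  Mode indices run over
#' the Hermitian-symmetric set `alpha, beta in {-alpha_max, ..., alpha_max - 1}`
#' (DFT wrap-around ordering), so a real height field is representable and the
#' wavelength cutoffs are `lambda_max = L` and `lambda_min = L / alpha_max`.
#'
#' @param config a [sim_config()] object, or a box side length `L` if
#'   `alpha_max` is given.
#' @param alpha_max mode cutoff, only when `config` is a plain length.
#' @return An object of class `"wave_grid"`: list with `N`, `L`, `dx`,
#'   `lambda_min`, matrices `qx`, `qy`, `qmag` (nm^-1) in DFT layout
#'   (first index = x), and the integer mode indices `alpha`.
#' @export
wave_grid <- function(config, alpha_max = NULL) {
  if (inherits(config, "sim_config")) {
    L <- config$L
    alpha_max <- config$alpha_max
  } else {
    L <- config
    if (is.null(alpha_max)) stop("alpha_max required when config is a length")
  }
  alpha_max <- as.integer(alpha_max)
  if (alpha_max < 1) stop("alpha_max must be a positive integer")
  N <- 2L * alpha_max
  a <- c(0:(N / 2 - 1), -(N / 2):-1)  # DFT wrap-around ordering
  qunit <- 2 * pi / L
  qx <- matrix(qunit * a, N, N)         # varies along rows (x index)
  qy <- matrix(qunit * a, N, N, byrow = TRUE)
  structure(list(N = N, L = L, dx = L / N, lambda_min = L / alpha_max,
                 alpha = a, qx = qx, qy = qy,
                 qmag = sqrt(qx^2 + qy^2)),
            class = "wave_grid")
}

#' @export
print.wave_grid <- function(x, ...) {
  cat(sprintf("<wave_grid> N = %d, L = %g nm, dx = %g nm, lambda in [%g, %g] nm\n",
              x$N, x$L, x$dx, x$lambda_min, x$L))
  invisible(x)
}

#' Zero-valued spectral field on a grid
#' @param grid a [wave_grid()].
#' @return complex `N x N` matrix of zeros.
#' @export
spectral_zero <- function(grid) {
  matrix(complex(real = 0), grid$N, grid$N)
}

#' Test Hermitian symmetry of a spectral field
#'
#' A spectral field representing a real height field must satisfy
#' `h_{-q} = Conj(h_q)`.
#'
#' @param hq complex `N x N` matrix.
#' @param tol relative tolerance.
#' @return logical.
#' @export
is_hermitian_field <- function(hq, tol = 1e-8) {
  scale <- max(Mod(hq), 1e-300)
  max(Mod(hq - conj_reflect(hq))) <= tol * scale
}

# h_{-q} companion of each mode: index reversal modulo N in both dimensions
conj_reflect <- function(hq) {
  N <- nrow(hq)
  idx <- c(1L, N:2L)
  Conj(hq[idx, idx, drop = FALSE])
}

#' Inverse transform: spectral field to real heights
#'
#' Uses the continuum convention `h(x) = L^-2 sum_q h_q exp(i q.x)`, i.e.
#' the unnormalised inverse DFT divided by `L^2`.
#'
#' @param hq complex `N x N` spectral field (nm^3).
#' @param grid a [wave_grid()].
#' @param on_asymmetry what to do if `hq` is not Hermitian-symmetric:
#'   `"error"` (default), `"warn"` (symmetrize and continue), or `"ignore"`.
#' @return real `N x N` matrix of heights (nm).
#' @export
to_real <- function(hq, grid, on_asymmetry = c("error", "warn", "ignore")) {
  on_asymmetry <- match.arg(on_asymmetry)
  if (on_asymmetry != "ignore" && !is_hermitian_field(hq)) {
    if (on_asymmetry == "error")
      stop("spectral field is not Hermitian-symmetric; real height undefined")
    warning("spectral field not Hermitian-symmetric; symmetrizing")
    hq <- (hq + conj_reflect(hq)) / 2
  }
  Re(stats::fft(hq, inverse = TRUE)) / grid$L^2
}

#' Forward transform: real heights to spectral field
#'
#' Discretization of `h_q = int h(x) exp(-i q.x) dx` as `(L/N)^2` times the
#' unnormalised DFT, the exact inverse of [to_real()].
#'
#' @param h real `N x N` height matrix (nm).
#' @param grid a [wave_grid()].
#' @return complex `N x N` spectral field (nm^3).
#' @export
to_fourier <- function(h, grid) {
  if (!all(is.finite(h))) stop("height field contains non-finite values")
  stats::fft(h) * grid$dx^2
}

#' Draw a spectral field from the free-membrane equilibrium ensemble
#'
#' Samples each bending mode from its stationary Gaussian,
#' `<|h_q|^2> = kBT L^2 / (B q^4)` (equipartition of the Helfrich
#' Hamiltonian), with the centre-of-mass mode set to `h0`.  Used to
#' initialise free-membrane runs in equilibrium, which removes the long
#' transient of the slowest modes.  Draws from R's RNG.
#'
#' @param grid a [wave_grid()].
#' @param B bending rigidity (pN nm).
#' @param kBT thermal energy (pN nm).
#' @param h0 mean height (nm), default 0.
#' @return Hermitian-symmetric complex `N x N` spectral field.
#' @export
equilibrium_spectrum <- function(grid, B, kBT, h0 = 0) {
  N <- grid$N
  sd_q <- sqrt(kBT * grid$L^2 / (B * grid$qmag^4))
  sd_q[1, 1] <- 0
  w <- matrix(stats::rnorm(N * N), N, N)
  hq <- (sd_q / N) * stats::fft(w)
  hq[1, 1] <- complex(real = h0 * grid$L^2)
  hq
}
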