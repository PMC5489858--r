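#' Block-averaged standard error
#'
#' Splits a (possibly autocorrelated) series into `n_blocks` contiguous
#' blocks and reports the standard error of the block means.  Honest only
#' when the block length exceeds the autocorrelation time of the series.
#'
#' @param x numeric series.
#' @param n_blocks number of blocks (>= 2).
#' @return list: `mean`, `se`, `n_blocks`.
#' @export
block_se <- function(x, n_blocks = 20L) {
  n <- length(x)
  n_blocks <- max(2L, min(as.integer(n_blocks), n))
  per <- n %/% n_blocks
  if (per < 1) stop("series too short for ", n_blocks, " blocks")
  x <- x[seq_len(per * n_blocks)]
  bm <- colMeans(matrix(x, nrow = per))
  list(mean = mean(bm), se = stats::sd(bm) / sqrt(n_blocks),
       n_blocks = n_blocks)
}

#' Analytic RMS height of a free membrane
#'
#' Continuum estimate of the spatial RMS of the out-of-plane fluctuation,
#' `sqrt(<h^2>) = sqrt(A kBT / (4 pi^3 B))` with `A = L^2`.
#'
#' @param L box side (nm).
#' @param B bending rigidity (pN nm).
#' @param kBT thermal energy (pN nm).
#' @return RMS height (nm).
#' @export
rms_height_analytic <- function(L, B, kBT) {
  sqrt(L^2 * kBT / (4 * pi^3 * B))
}

#' Relative fluctuation amplitude of a free membrane
#'
#' `sqrt(<h^2>) / L = sqrt(kBT / (4 pi^3 B))`, dimensionless.
#'
#' @inheritParams rms_height_analytic
#' @return relative amplitude.
#' @export
relative_amplitude <- function(B, kBT) {
  sqrt(kBT / (4 * pi^3 * B))
}

#' Exact discrete-mode RMS height of a free membrane
#'
#' Equipartition summed over the actual simulated mode set:
#' `<h^2> = L^-4 sum_q kBT L^2 / (B q^4)` over all modes of a
#' [wave_grid()] with cutoff `alpha_max`.  The continuum formula
#' [rms_height_analytic()] differs from this lattice sum by an O(1) factor
#' because the integral approximation is poor for the few slowest modes
#' that dominate the variance.
#'
#' @inheritParams rms_height_analytic
#' @param alpha_max mode cutoff.
#' @return RMS height (nm).
#' @export
rms_height_modes <- function(L, B, kBT, alpha_max) {
  grid <- wave_grid(L, alpha_max)
  q4 <- grid$qmag^4
  q4[1, 1] <- Inf
  sqrt(sum(kBT / (B * q4)) / L^2)
}

#' Relaxation time of a bending mode
#'
#' Characteristic decay time of a free bending mode of wavelength `lambda`:
#' `tau = 4 eta lambda^3 / (B (2 pi)^3)`.
#'
#' @param lambda mode wavelength (nm).
#' @param B bending rigidity (pN nm).
#' @param eta viscosity (pN ns / nm^2).
#' @return relaxation time (ns).
#' @export
mode_relaxation_time <- function(lambda, B, eta) {
  4 * eta * lambda^3 / (B * (2 * pi)^3)
}

#' Radially binned fluctuation spectrum
#'
#' Time-averages the sampled mode powers `|h_q|^2` of a trajectory and bins
#' them radially in `|q|` (bin width `2 pi / L`, the mode spacing).  The
#' standard error per bin is block-averaged over time after averaging over
#' the modes in the bin.  The equipartition reference
#' `<|h_q|^2> = kBT L^2 / (B q^4)`, averaged over the same modes, is
#' attached as `theory`.
#'
#' @param traj an `"fsbd_trajectory"` run with `spectrum_stride > 0`, or a
#'   plain `N x N x n` array of `|h_q|^2` samples (then `grid`, `B`, `kBT`
#'   must be given).
#' @param grid,B,kBT taken from `traj` when it is a trajectory.
#' @param discard_frac initial fraction of samples discarded as burn-in.
#' @param n_blocks blocks for the standard error.  For a trajectory the
#'   default (`NULL`) chooses the count per bin so each block spans at
#'   least three autocorrelation times of that bin's own mode power
#'   (`tau_int = tau_q / 2`, from the known relaxation times): slow bins
#'   get few long blocks, fast bins get up to 50 short ones, which keeps
#'   block means independent while giving the error estimate itself enough
#'   degrees of freedom.  For a plain array the default is a fixed 10.
#' @param min_samples minimum retained samples required.
#' @return data.frame: `q` (bin-mean |q|, nm^-1), `power` (nm^6), `se`,
#'   `n_modes`, `theory`.
#' @export
fluctuation_spectrum <- function(traj, grid = NULL, B = NULL, kBT = NULL,
                                 discard_frac = 0.2, n_blocks = NULL,
                                 min_samples = 100L) {
  if (inherits(traj, "fsbd_trajectory")) {
    if (is.null(traj$spectrum))
      stop("trajectory has no spectrum samples (run with spectrum_stride > 0)")
    grid <- traj$grid
    B <- traj$config$B
    kBT <- traj$config$kBT
    arr <- traj$spectrum
    eta <- traj$config$eta
    t_span <- traj$config$t_total * (1 - discard_frac)
  } else {
    arr <- traj
    if (is.null(grid) || is.null(B) || is.null(kBT))
      stop("grid, B and kBT are required for a plain power array")
    eta <- NULL
    t_span <- NA_real_
    if (is.null(n_blocks)) n_blocks <- 10L
  }
  ns <- dim(arr)[3]
  keep <- seq.int(floor(discard_frac * ns) + 1L, ns)
  if (length(keep) < min_samples)
    stop("need at least ", min_samples, " retained spectrum samples, have ",
         length(keep))
  arr <- arr[, , keep, drop = FALSE]
  ns <- dim(arr)[3]

  dq <- 2 * pi / grid$L
  bin <- round(grid$qmag / dq)
  bin[1, 1] <- -1                      # exclude the zero mode
  bins <- sort(unique(bin[bin > 0L]))

  flat <- matrix(arr, nrow = grid$N^2, ncol = ns)
  out <- lapply(bins, function(b) {
    sel <- which(bin == b)
    series <- colMeans(flat[sel, , drop = FALSE])
    nb <- n_blocks
    if (is.null(nb)) {
      # block length >= 3 integrated autocorrelation times of this bin's
      # slowest mode power, tau_int = tau_q / 2
      tau_int <- mode_relaxation_time(2 * pi / min(grid$qmag[sel]), B, eta) / 2
      nb <- max(4L, min(50L, as.integer(floor(t_span / (3 * tau_int)))))
    }
    bs <- block_se(series, nb)
    data.frame(q = mean(grid$qmag[sel]), power = bs$mean, se = bs$se,
               n_modes = length(sel), n_blocks = bs$n_blocks,
               theory = mean(kBT * grid$L^2 / (B * grid$qmag[sel]^4)))
  })
  do.call(rbind, out)
}

#' Mean membrane-substrate gap
#'
#' Time average of the spatial mean height above the wall truncation plane,
#' `d = <mean(h) - h_sub>`, over the equilibrated part of a trajectory.
#'
#' @param traj an `"fsbd_trajectory"`.
#' @param h_sub reference plane (default from the trajectory's config).
#' @param discard_frac initial fraction discarded as burn-in.
#' @param n_blocks blocks for the standard error.
#' @return list: `d` (nm), `se`, `n`.  A negative `d` triggers a warning
#'   (membrane penetrating the wall; the run is likely unstable).
#' @export
mean_gap <- function(traj, h_sub = traj$config$h_sub, discard_frac = 0.2,
                     n_blocks = 20L) {
  x <- traj$samples$mean_height
  keep <- seq.int(floor(discard_frac * length(x)) + 1L, length(x))
  bs <- block_se(x[keep] - h_sub, n_blocks)
  if (bs$mean < 0)
    warning("negative mean gap: membrane penetrates the wall plane")
  list(d = bs$mean, se = bs$se, n = length(keep))
}

#' Time-averaged closed bond ratio
#'
#' Mean of `phi` (closed bonds / total receptors) over the equilibrated
#' part of a trajectory, with a block-averaged (autocorrelation-aware)
#' standard error.
#'
#' @param traj an `"fsbd_trajectory"` run with kinetics, or a numeric `phi`
#'   series.
#' @param discard_frac initial fraction discarded as burn-in.
#' @param n_blocks blocks for the standard error.
#' @return list: `phi`, `se`, `n`.
#' @export
closed_bond_ratio_series <- function(traj, discard_frac = 0.2,
                                     n_blocks = 20L) {
  x <- if (inherits(traj, "fsbd_trajectory")) traj$samples$phi else traj
  if (anyNA(x)) stop("phi series contains NA (was the run made with kinetics?)")
  keep <- seq.int(floor(discard_frac * length(x)) + 1L, length(x))
  bs <- block_se(x[keep], n_blocks)
  list(phi = bs$mean, se = bs$se, n = length(keep))
}

#' Helfrich entropic pressure law
#'
#' `p = c (kBT)^2 / (B d^3)`: the repulsion of a thermally fluctuating
#' membrane confined at mean distance `d` from a hard wall.
#'
#' @param d gap (nm).
#' @param B bending rigidity (pN nm).
#' @param kBT thermal energy (pN nm).
#' @param c dimensionless coefficient.
#' @return pressure (pN/nm^2).
#' @export
entropic_pressure <- function(d, B, kBT, c = 0.078) {
  c * kBT^2 / (B * d^3)
}

#' Fit the entropic-pressure coefficient
#'
#' Least-squares fit of `c` in `p = c (kBT)^2 / (B d^3)` on log scales with
#' the exponent fixed at -3: the intercept of `log p + 3 log d` gives `c`.
#'
#' @param curve data.frame with columns `p` (pN/nm^2) and `d` (nm), one row
#'   per applied pressure.
#' @param B bending rigidity (pN nm).
#' @param kBT thermal energy (pN nm).
#' @return fitted dimensionless `c`.
#' @export
fit_entropic_coefficient <- function(curve, B, kBT) {
  if (!all(c("p", "d") %in% names(curve)))
    stop("curve must have columns p and d")
  if (nrow(curve) < 3) stop("need at least 3 (p, d) points to fit c")
  if (any(curve$p <= 0) || any(curve$d <= 0))
    stop("pressures and gaps must be positive")
  o <- order(curve$p)
  if (any(diff(curve$d[o]) >= 0))
    stop("pressure-distance curve is not monotone (d must fall as p rises)")
  intercept <- mean(log(curve$p) + 3 * log(curve$d))
  B / kBT^2 * exp(intercept)
}
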