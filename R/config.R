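#' Simulation configuration
#'
#' Collects every physical, numerical and kinetic parameter of the
#' membrane-substrate model in a fixed unit system: lengths in nm, times in
#' ns, forces in pN, energies in pN nm.  Viscosities quoted in Poise convert
#' as 1 Poise = 100 pN ns / nm^2 (see [poise()]).
#'
#' @param L box side length (nm); the membrane is periodic on an L x L square.
#' @param alpha_max integer mode cutoff; the shortest resolved wavelength is
#'   `lambda_min = L / alpha_max` and the collocation grid has
#'   `N = 2 * alpha_max` points per side.
#' @param B bending rigidity (pN nm).
#' @param eta viscosity of the surrounding fluid (pN ns / nm^2); 0.06 Poise
#'   of water-like cytosol is `poise(0.06) = 6`.
#' @param kBT thermal energy (pN nm); 4.3 pN nm at room temperature.
#' @param dt integration timestep (ns).  Keep it roughly two orders of
#'   magnitude below the relaxation time of the shortest wavelength mode,
#'   [mode_relaxation_time()].
#' @param t_total total simulated time (ns).
#' @param seed integer RNG seed; a run is fully reproducible given
#'   (config, seed).
#' @param sigma_w soft-wall length scale (nm).
#' @param eps_w soft-wall strength (pN/nm, an energy per unit area).
#' @param h_sub wall truncation height (nm): the repulsion acts only where
#'   the membrane is at or below `h_sub`.
#' @param k membrane-substrate linkage spring constant (pN/nm); lumps bilayer
#'   shear, receptor-ligand complex stiffness and substrate elasticity, so
#'   sweeping `k` emulates sweeping substrate rigidity.
#' @param h_L rest height of an unbound ligand (nm).
#' @param Delta receptor spacing (nm); must be an integer multiple of the
#'   collocation spacing `L / N` so receptors sit on grid points.
#' @param Nb receptors per side (the lattice has `Nb^2` receptors); defaults
#'   to `floor(L / Delta)`.
#' @param R_RL encounter distance (nm): an open bond can close only while the
#'   receptor-ligand separation `|h(x_mn) - h_L|` is within `R_RL`.
#' @param kon0 intrinsic single-molecule on-rate (1/ns).
#' @param koff0 zero-force off-rate (1/ns).
#' @param x_b Bell length (nm) controlling force-accelerated unbinding,
#'   `koff = koff0 * exp(f * x_b / kBT)`.
#' @param p applied uniform pressure (pN/nm^2); positive pushes the membrane
#'   toward the substrate.
#' @param h_init initial flat membrane height (nm); defaults to
#'   `h_L + R_RL` so binding can nucleate.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @export
sim_config <- function(L = 800, alpha_max = 40, B = 20, eta = poise(0.06),
                       kBT = 4.3, dt = 0.5, t_total = 1e5, seed = 1L,
                       sigma_w = 4, eps_w = 0.043, h_sub = 0,
                       k = 10, h_L = -1.2, Delta = 20, Nb = NULL,
                       R_RL = 1, kon0 = 1, koff0 = 1e-4, x_b = 1,
                       p = 0, h_init = NULL) {
  if (is.null(Nb)) Nb <- as.integer(floor(L / Delta))
  if (is.null(h_init)) h_init <- h_L + R_RL
  cfg <- structure(
    list(L = L, alpha_max = as.integer(alpha_max), B = B, eta = eta,
         kBT = kBT, dt = dt, t_total = t_total, seed = as.integer(seed),
         sigma_w = sigma_w, eps_w = eps_w, h_sub = h_sub,
         k = k, h_L = h_L, Delta = Delta, Nb = as.integer(Nb),
         R_RL = R_RL, kon0 = kon0, koff0 = koff0, x_b = x_b,
         p = p, h_init = h_init),
    class = "sim_config")
  validate_config(cfg)
  cfg
}

#' Convert a viscosity from Poise to pN ns / nm^2
#'
#' 1 Poise = 0.1 Pa s and 1 Pa s = 1000 pN ns / nm^2, hence the factor 100.
#' @param x viscosity in Poise.
#' @return viscosity in pN ns / nm^2.
#' @export
poise <- function(x) 100 * x

#' Validate a simulation configuration
#'
#' Checks positivity, the mode-cutoff relations `lambda_min = L/alpha_max`
#' and `lambda_max = L`, registration of the receptor lattice with the
#' collocation grid, and first-order Monte Carlo validity of the kinetic
#' rates (`kon0 * dt < 0.1`, warning otherwise).
#'
#' @param cfg a `"sim_config"` object.
#' @return `cfg`, invisibly; stops on an invalid configuration.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (!(L > 0)) stop("L must be positive")
    if (!(alpha_max >= 1)) stop("alpha_max must be a positive integer")
    if (!(dt > 0)) stop("dt must be positive")
    if (!(B > 0 && eta > 0)) stop("B and eta must be positive")
    if (kBT < 0) stop("kBT must be non-negative")
    if (t_total < 0) stop("t_total must be non-negative")
    if (any(c(kon0, koff0) < 0)) stop("rates must be non-negative")
    if (sigma_w <= 0) stop("sigma_w must be positive")
    if (eps_w < 0) stop("eps_w must be non-negative")
    if (Nb >= 1) {
      N <- 2L * alpha_max
      dxg <- L / N
      if (abs(Delta / dxg - round(Delta / dxg)) > 1e-9)
        stop("Delta must be an integer multiple of the grid spacing L/N = ",
             signif(dxg, 6), " nm")
      if (Nb * Delta > L + 1e-9)
        stop("receptor lattice exceeds the box: Nb * Delta must be <= L")
    }
    if (kon0 * dt >= 0.1)
      warning("kon0 * dt = ", signif(kon0 * dt, 3),
              " >= 0.1: first-order Monte Carlo kinetics may be inaccurate")
    invisible(NULL)
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>  (nm / ns / pN units)\n")
  cat(sprintf("  box L = %g nm, alpha_max = %d (lambda_min = %g nm, N = %d)\n",
              x$L, x$alpha_max, x$L / x$alpha_max, 2L * x$alpha_max))
  cat(sprintf("  B = %g pN nm, kBT = %g pN nm, eta = %g pN ns/nm^2\n",
              x$B, x$kBT, x$eta))
  cat(sprintf("  dt = %g ns, t_total = %g ns (%g steps), seed = %d\n",
              x$dt, x$t_total, x$t_total / x$dt, x$seed))
  cat(sprintf("  wall: sigma_w = %g nm, eps_w = %g pN/nm, h_sub = %g nm; p = %g pN/nm^2\n",
              x$sigma_w, x$eps_w, x$h_sub, x$p))
  cat(sprintf("  linkage: k = %g pN/nm, h_L = %g nm, Delta = %g nm, Nb = %d\n",
              x$k, x$h_L, x$Delta, x$Nb))
  cat(sprintf("  kinetics: kon0 = %g /ns, koff0 = %g /ns, x_b = %g nm, R_RL = %g nm\n",
              x$kon0, x$koff0, x$x_b, x$R_RL))
  invisible(x)
}

#' Modify a configuration
#'
#' Returns a revalidated copy of `cfg` with the named fields replaced.
#' `Nb` is re-derived from `Delta` unless given explicitly.
#'
#' @param cfg a `"sim_config"` object.
#' @param ... named fields to replace.
#' @return a new `"sim_config"`.
#' @export
update_config <- function(cfg, ...) {
  changes <- list(...)
  bad <- setdiff(names(changes), names(unclass(cfg)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(changes)) cfg[[nm]] <- changes[[nm]]
  # re-derive the receptor count from the updated box and spacing
  if (any(c("Delta", "L") %in% names(changes)) && !("Nb" %in% names(changes)))
    cfg$Nb <- as.integer(floor(cfg$L / cfg$Delta))
  cfg$alpha_max <- as.integer(cfg$alpha_max)
  cfg$Nb <- as.integer(cfg$Nb)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

#' Parse a flat key = value configuration file
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored.  Keys must be `sim_config` field names; values are parsed as
#' numbers.
#'
#' @param path file path.
#' @param base configuration to override (default [sim_config()] defaults).
#' @return a `"sim_config"`.
#' @export
read_config_file <- function(path, base = sim_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) != 2L]
  if (length(bad)) stop("malformed config line: ", bad[[1]])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric config value for key: ",
                        keys[which(is.na(vals))[1]])
  do.call(update_config, c(list(cfg = base), as.list(stats::setNames(vals, keys))))
}
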