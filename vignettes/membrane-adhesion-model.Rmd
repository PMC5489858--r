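---
title: "Fluctuating-membrane adhesion: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuating-membrane adhesion: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsbdmc)
```

## The physical model

`fsbdmc` simulates the early stage of cell-substrate adhesion: a lipid
membrane, thermally undulating above an elastic substrate, forms and breaks
receptor-ligand bonds with ligands anchored in the substrate.  Adhesion is a
two-step reaction: the out-of-plane membrane fluctuation carries an immobile
receptor to within the encounter distance $R_{RL}$ of its ligand, and the
encounter then reacts to a closed bond with intrinsic rate $k_{on}^0$.
Closed bonds dissociate at the Bell (slip-bond) rate

$$k_{off} = k_{off}^0 \exp\!\left(\frac{f x_b}{k_B T}\right),$$

where $f$ is the tension the membrane exerts on the bond.  The adhesion
strength observable is the closed bond ratio $\phi$, the number of closed
bonds over the number of receptors.

The membrane is a Monge-gauge height field $h(\mathbf{x})$ on a periodic
$L \times L$ square, with Canham-Helfrich bending energy
$E_b = \tfrac{B}{2}\int (\nabla^2 h)^2\,d\mathbf{x}$.  Its Fourier
amplitudes $h_{\mathbf q} = \int h\, e^{-i \mathbf q\cdot\mathbf x} d\mathbf x$
obey overdamped Langevin dynamics

$$\frac{\partial h_{\mathbf q}}{\partial t}
   = \Lambda_q \left[ F_{\mathbf q}(t) + \zeta_{\mathbf q}(t) \right],
  \qquad \Lambda_q = \frac{1}{4 \eta q},$$

with Gaussian noise of covariance
$\langle \zeta_{\mathbf q} \zeta_{\mathbf q'}^* \rangle
 = 2 k_B T L^2 \Lambda_q^{-1} \delta_{\mathbf q \mathbf q'} \delta(t-t')$,
so each bending mode equilibrates to the equipartition variance
$\langle |h_{\mathbf q}|^2 \rangle = k_B T L^2 / (B q^4)$.  Four
deterministic forces act:

* bending, $F^b_{\mathbf q} = -B q^4 h_{\mathbf q}$;
* harmonic membrane-substrate linkages of stiffness $k$ at each closed
  bond, $F^L_{\mathbf q} = -\sum_{mn} \phi_{mn}\, k\,[h(\mathbf x_{mn}) - h_L]
  e^{-i\mathbf q\cdot\mathbf x_{mn}}$, where the lumped spring $k$ combines
  bilayer shear, complex stiffness and substrate elasticity - sweeping $k$
  emulates sweeping substrate rigidity;
* a truncated soft-wall substrate repulsion with pointwise pressure
  $8(\varepsilon_w/\sigma_w)\,[\sigma_w/(h+\sigma_w-h_{sub})]^9$ for
  $h \le h_{sub}$ and zero above;
* a uniform holding pressure, $F^p_{\mathbf q} = -L^2 p\, \delta_{\mathbf q,0}$.

Everything is expressed in nm, ns, pN and pN nm; a viscosity quoted in
Poise converts via `poise()` (1 Poise = 100 pN ns/nm^2), so water-like
0.06 Poise is 6 pN ns/nm^2.

## Discretisation

**Mode set.**  A cutoff $\alpha_{max}$ fixes the resolved wavelengths
between $\lambda_{min} = L/\alpha_{max}$ and $\lambda_{max} = L$.  A real
height field needs conjugate mode pairs, so the package uses the full
Hermitian-symmetric DFT set $\alpha, \beta \in \{-\alpha_{max}, \dots,
\alpha_{max}-1\}$ on an $N = 2\alpha_{max}$ collocation grid; this keeps
both cutoffs while guaranteeing $h(\mathbf{x})$ real.  Transforms use the
continuum normalisation $h_{\mathbf q} = (L/N)^2\,\mathrm{DFT}(h)$ so the
force expressions above apply verbatim.

**Zero mode.**  The Oseen mobility diverges as $q \to 0$.  The
centre-of-mass mode is given the box-scale mobility
$\Lambda_0 = 1/(4\eta \cdot 2\pi/L)$ and no thermal kick: it drifts only
under the deterministic wall/pressure balance.  A free membrane therefore
keeps its mean height; confined runs equilibrate the mean gap through the
wall.

**Integration.**  Explicit Euler-Maruyama.  Stability requires
$\Delta t$ about two orders of magnitude below the relaxation time
$\tau = 4\eta\lambda^3/(B(2\pi)^3)$ of the shortest mode
(`mode_relaxation_time()`; 38.7 ns for $\lambda_{min} = 20$ nm at the
reference parameters).  Accuracy is a separate constraint: Euler inflates
each mode's stationary variance by a factor
$\approx 1 + \Delta t/(2\tau_q)$.  At $\Delta t = 0.5$ ns this is a 1-2%
bias on the fastest modes - invisible in short runs but well resolved by
the long spectrum-validation average, which is why the quick validation
preset integrates at $\Delta t = 0.05$ ns while adhesion runs use 0.25 ns
(the ninth-power wall is stiffer at contact than any bending mode, so they
also stay below the paper-style 0.5 ns).

**Wall.**  The wall pressure is evaluated pointwise on the collocation
grid and transformed (pseudo-spectral collocation).  The truncation at
$h_{sub}$ is implemented literally, so the wall force steps from
$8\varepsilon_w/\sigma_w$ to zero there; $\varepsilon_w$ is small, so the
jump is mild.  If any grid point reaches $h \le h_{sub} - \sigma_w$ the
step aborts with a timestep-stability error rather than integrating
through the singularity.

**Noise.**  Increments are drawn directly per Hermitian mode pair (two
independent real Gaussians per pair, one per self-conjugate mode), which
realises the required covariance exactly on every mode, including the
Nyquist ones.  The production engine (`fsbd_run(engine = "cpp")`) runs its
own counter-seeded generator initialised from R's RNG, so a trajectory is
fully determined by `(config, seed)`; the pure-R reference engine
(`engine = "r"`) implements the identical update and is cross-checked
against the production engine exactly on deterministic runs.

**Bond kinetics.**  One Monte Carlo sweep per timestep, sites visited in
fixed row-major order: open bonds close with probability
$k_{on}^0 \Delta t$ while $|h(\mathbf x_{mn}) - h_L| \le R_{RL}$, closed
bonds open with probability $k_{off}\Delta t$ (clamped at one, with a
warning counter).  Fixed visiting order is deterministic and unbiased here
because per-step probabilities are small.  The bond force is tension-only,
$f = k \max(h - h_L, 0)$: the membrane "pulls" bonds open, and compression
accelerating rupture would be unphysical for a slip bond.  Rebinding is
instantaneous - the substrate is rigid on membrane time scales, so a
released ligand recoils to rest immediately.

## Parameter choices

The reference membrane is $B = 20$ pN nm ($\approx 5\,k_BT$),
$k_BT = 4.3$ pN nm, $\eta = 0.06$ Poise, $\lambda_{min} = 20$ nm.
Adhesion runs (`adhesion_config()`) use the holding pressure
$p = 4\times10^{-5}$ pN/nm^2 (required: the entropic repulsion would
otherwise push the membrane away from the substrate), $h_L = -1.2$ nm,
$\sigma_w = 4$ nm and $\varepsilon_w = 0.043$ pN/nm
($= 0.01\,k_BT$/nm^2).  Intrinsic rates sit at their upper physiological
bounds, $k_{on}^0 = 1$/ns and $k_{off}^0 = 10^{-4}$/ns: their ratio
$10^4 = e^{10}$ corresponds to a 10 $k_BT$ binding energy, and fast
intrinsic kinetics are what make the overall reaction
fluctuation-limited, hence substrate-rigidity-sensitive.  Receptors sit
on a lattice registered with the collocation grid ($\Delta$ must be a
multiple of $L/N$), so site heights need no interpolation.

Two quantities the model needs have no measured values for a lumped
linkage and are exposed as plain configuration keys: the encounter
distance `R_RL` and the Bell length `x_b`.  Their defaults
(`R_RL = 2` nm, `x_b = 0.5` nm, with `Delta = 10` nm) were calibrated
once, on scans of the scaled 240 nm box, to place the coupled system in
its smoothly adhered regime.  That calibration matters because the small
box exaggerates an instability of the model: adhesion here is bistable
(a pinned branch held by closed bonds and a detached branch held off the
wall by entropic repulsion), and in a 240 nm box the membrane flips
globally between the branches instead of showing the partial, patchy
detachment a micron-scale membrane exhibits.  With a sparse lattice, a
short encounter distance, or a long Bell length, stiffness sweeps
collapse abruptly to the detached branch at moderate $k$ (an absorbing
escape, since rebinding needs a rare deep excursion) rather than tracing
a smooth crossover.  The defaults keep every sweep point on the adhered
branch; the sweeps themselves stay fully configurable.

Initial conditions: `fsbd_run()` starts a flat membrane at `h_init`
(default $h_L + R_{RL}$, so binding can nucleate) with all bonds open.
The adhesion sweeps override this and start fully adhered (all bonds
closed, membrane at $h_L$): they measure the equilibrium of the adhered
state, and at 100-fold reduced rates nucleation from a detached start is
itself a slow process that would dominate the run; at the fast default
rates the steady state is verifiably the same from either start.
Free-membrane validation runs can instead start from an exact
equilibrium spectrum draw (`equilibrium_spectrum()`), which removes the
$\tau(\lambda = L)$ transient - about 67 us at $L = 240$ nm - and lets
the whole run sample in stationarity.

## Problem sizes used in the shipped experiments

All scripted experiments run on a desk scale chosen to finish in minutes
while keeping every estimate statistically resolved; they are the
package's own defaults, stated here so results can be reproduced exactly.

* *Free-membrane spectrum* (quick preset): $L = 240$ nm,
  $\alpha_{max} = 12$ ($N = 24$), $\Delta t = 0.05$ ns, 1 ms total
  ($2\times10^7$ steps), spectrum sampled every 100 ns, first 20%
  discarded.  Spectrum standard errors are block averages with per-bin
  block lengths of at least three autocorrelation times of that bin's
  slowest mode power ($\tau_{int} = \tau_q/2$, up to $\approx 33$ us for
  the $\lambda = L$ bin).
* *Entropic pressure sweep*: same box, $\sigma_w = 2$ nm,
  $\Delta t = 0.25$ ns, five pressures $(1,2,4,8,16)\times10^{-4}$
  pN/nm^2, 0.3 ms each.  The box is smaller than the reference 800 nm;
  the pressure-distance relation is insensitive to box size at fixed
  $\lambda_{min}$, and the gaps probed ($d \approx 3$-$9$ nm) stay small
  against the box while large against $\sigma_w$.  Each run starts at the
  gap predicted by the law itself with $c = 0.1$ (a starting guess only;
  burn-in is discarded, and a first-half/second-half drift test flags
  unequilibrated runs).
* *Adhesion sweeps*: $\Delta t = 0.25$ ns, 0.2 ms per point
  ($8\times10^5$ steps, about 20 zero-force bond lifetimes), stiffness
  grid 0.3-30 pN/nm (two decades; beyond $k \approx 50$ the scaled box
  leaves the adhered branch, see above), spacings $\Delta = 10$-$40$ nm.

## What the validations do and do not show

The free-membrane spectrum test checks the integrator against
equipartition mode by mode, and the fixed-gap bond test checks the Monte
Carlo kinetics against the exact two-state occupancy
$k_{on}^0/(k_{on}^0 + k_{off}(f))$ - together they validate the two
halves of the coupled scheme independently before the coupled experiments
are interpreted.  The entropic sweep reproduces the classic confined-
membrane repulsion $p = c (k_BT)^2/(B d^3)$ with $c$ near 0.078 in the
hard-wall regime; the fitted $c$ is sensitive to $\lambda_{min}$ and
softens with larger $\sigma_w$, which is why the sweep pins
$\lambda_{min} = 20$ nm and a small $\sigma_w$.

On the spatial amplitude, note a cutoff effect: the textbook estimate
$\langle h^2 \rangle \approx A k_BT/(4\pi^3 B)$ (33 nm RMS for the
reference 800 nm membrane, `rms_height_analytic()`) replaces the discrete
mode sum by a continuum integral, which is a poor approximation for the
handful of slowest modes that dominate the variance.  The exact sum over
the simulated mode set (`rms_height_modes()`) is about 31% lower at these
cutoffs, and it - not the continuum formula - is what simulations agree
with to within sampling error.  Both estimators are exported; the ratio
is reported by `run_free_membrane()`.

These are simulations of the model, not of a cell: receptors do not
diffuse in-plane (dilute receptors, saturated ligands), the linkage is a
linear spring, the membrane carries no tension term, and nothing
downstream of nascent adhesions (clustering, cytoskeleton) is
represented.  The adhesion trends - a maximum of $\phi$ at intermediate
stiffness, the gap shrinking with stiffness, $\phi$ falling with receptor
spacing, and the rigidity dependence weakening at slow intrinsic rates -
are statements about this model's equilibrium, established here under the
scaled problem sizes above with block-averaged errors.

## Known limitations

* Explicit Euler with the literal wall truncation means very stiff walls
  (small $\sigma_w$) need small timesteps; the integrator detects and
  reports penetration rather than silently diverging.
* The $q = 0$ mobility regularisation is a modelling choice where the
  hydrodynamic limit is genuinely singular; mean-gap dynamics (not
  statics) depend on it.
* Standard errors come from block averaging; for observables whose
  correlation time approaches a fifth of the run (the $\lambda = L$ mode
  power in short runs) they are noisy, and the estimators refuse runs
  with too few samples rather than report a precise-looking number.
* `koff * dt` is clamped at one; sweeps report how often the clamp fired,
  and a nonzero count means unbinding of the stiffest springs is not
  time-resolved (their equilibrium occupancy is still correct for the
  clamped two-state chain).
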