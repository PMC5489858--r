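Package: fsbdmc
Title: Fourier-Space Brownian Dynamics of Membrane Adhesion with Monte Carlo Bond Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a thermally fluctuating lipid membrane adhering to an
    elastic substrate through receptor-ligand bonds. The membrane height field
    evolves by overdamped Langevin dynamics in Fourier space (Helfrich bending
    forces, a truncated soft-wall substrate repulsion, harmonic
    membrane-substrate linkages, and a uniform holding pressure), while bond
    opening and closing follow fixed-timestep Monte Carlo kinetics with a
    Bell-model force-dependent off-rate. Includes estimators for fluctuation
    spectra, entropic (Helfrich) repulsion coefficients and closed-bond-ratio
    statistics, plus scripted experiments: free-membrane spectrum validation,
    entropic pressure-distance sweeps, and substrate-stiffness and
    receptor-density adhesion sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
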