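Package: qensllps
Title: Quasi-Elastic Neutron Spectra of Proteins Across Liquid-Liquid Phase
    Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and fits backscattering quasi-elastic neutron scattering
    (QENS) spectra of crowded protein solutions, with an emphasis on samples
    undergoing liquid-liquid phase separation (LLPS).  Provides the measured
    spectral model (center-of-mass and internal-dynamics Lorentzians, solvent
    term and elastic line, analytically convolved with a multi-Gaussian
    resolution function), simultaneous global fits in momentum and energy
    transfer with one or two diffusing populations and reduced chi-squared
    model selection, hard-sphere short-time hydrodynamics for apparent
    diffusion coefficients, Flory-Stockmayer cluster statistics, lever-rule
    phase bookkeeping, and a seeded synthetic-spectrum generator so that the
    whole pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    rlang,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
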