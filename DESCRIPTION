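Package: reflectsim
Title: Monte Carlo Tissue Reflectance Simulation and Neural Surrogate Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates diffuse reflectance of layered biological tissue with a
    multilayer Monte Carlo photon-transport engine (pencil beam,
    Henyey-Greenstein scattering, Fresnel boundaries, Russian roulette),
    parameterised by a physiological tissue model (hemoglobin absorption,
    Mie-type reduced scattering). Provides a binomial error model for Monte
    Carlo reflectance uncertainty, a multilayer-perceptron surrogate that
    regresses reflectance from per-layer optical properties, neural
    data-scaling experiments with power-law fitting, spectral-recall and PCA
    realism metrics for comparing simulated against measured spectra, camera
    spectral adaptation, and nearest-neighbour tissue-oxygenation (stO2)
    estimation on labelled hyperspectral cubes, including a synthetic cube
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lhs,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
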