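Package: desmix
Title: Analysis of Coarse-Grained Deep Eutectic Solvent Mixture Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing particle-based simulations of deep eutectic
    solvent (DES) mixtures and their transition to ionic liquids. Provides
    composition algebra with reaction-extent bookkeeping and solvent-regeneration
    mass balances, a simulation-campaign planner, contact-based miscibility
    scoring and classification, mean-squared-displacement diffusion analysis
    with finite-size extrapolation and survivor-bias-free per-phase estimates,
    thermal expansion from density series, shear viscosity via the periodic
    perturbation method, partial density profiles, radial distribution
    functions and phase-partition quantification. Includes a small Langevin
    soft-sphere mixture simulator and stochastic generators so every analysis
    stage can be exercised on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
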