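Package: thermevol
Title: Evolution of Thermal Sensitivity from Thermal Performance Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the four-parameter Sharpe-Schoolfield model to thermal
    performance curves (TPCs) of biological rates, applies data-quality
    filters to the resulting parameter estimates, and analyses how thermal
    sensitivity (the activation energy E and the operational niche width
    W_op) evolves across a time-calibrated phylogeny. Implements maximum
    likelihood estimation of Pagel's lambda (phylogenetic heritability)
    with optional measurement error, disparity-through-time curves with a
    rank-envelope test against Brownian-motion simulations, generalized
    least squares trend regressions on tip values plus Brownian ancestral
    states, latitudinal mixed models with marginal and conditional
    coefficients of determination, and Mantel tests between distance
    matrices. A synthetic-data module simulates birth-death trees, TPC
    parameters evolving under Brownian motion with optional jumps and
    trends, noisy measurement tables, and latitude assignments with known
    ground truth, so that the full pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    phytools,
    vegan,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
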