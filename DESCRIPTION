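Package: sasbayes
Title: Bayesian Model Selection for Small-Angle Scattering Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative selection of structural models for small-angle
    scattering (SAXS/SANS) count data. Implements a Poisson observation
    model for measured intensities, replica-exchange Monte Carlo sampling
    over an inverse-temperature ladder, stepping-stone estimation of the
    marginal likelihood (Bayesian free energy), posterior model
    probabilities across candidate mixtures of monodisperse spheres, MAP
    parameter estimates with posterior fit-curve envelopes, and a
    conventional reduced chi-squared selector as a baseline. Includes a
    synthetic-data generator for benchmark scenarios and a command-line
    interface for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
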