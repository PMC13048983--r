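Package: blinkHMM
Title: Bayesian Hidden Markov Analysis of Single-Molecule Fluorescence Blinking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers hidden ON/OFF state sequences from single-molecule
    fluorescence photon-count trajectories with a two-state Gaussian-emission
    hidden Markov model. Fitting uses blocked Gibbs sampling with exact
    forward-filtered backward sampling of the state sequence and closed-form
    conjugate updates (Gauss-Gamma emission, Dirichlet transition and initial
    distributions). Downstream tools turn inferred state sequences into
    blinking statistics: dwell-time probability densities, exponential
    relaxation-time fits, transition-matrix relaxation times, photon-count
    histogram models, time-bin diagnostics, and a mean-variance (Poisson)
    check. A synthetic-trajectory generator with Markov-switching Poisson or
    Gaussian count noise supports validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
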