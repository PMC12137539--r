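Package: spinalres
Title: Excitation-Inhibition Imbalance in Reservoir Models of Spinal Pattern Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the anatomical balance between excitatory
    and inhibitory populations shapes motor pattern formation in reservoir
    computing models of the spinal cord. Builds sparse Dale's-law random
    networks with a prescribed excitation-inhibition imbalance, solves the
    corresponding quasi-stationary mean-field theory (input mean and variance,
    firing-rate moments, stability of the driven state), trains linear
    readouts with recursive least squares (FORCE) to reproduce periodic
    multi-channel locomotor-like muscle activations, and quantifies network
    dynamics and motor-output quality (stride success rate, effective
    dimensionality, coactivation index, between-task variance, firing-rate
    statistics). Includes a synthetic generator for 17-channel locomotor
    targets and bell-shaped motor-primitive patterns, plus experiment drivers
    for imbalance sweeps, mean-field comparisons and speed-generalization
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    pracma,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
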