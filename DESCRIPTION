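Package: melcircuit
Title: Ensemble Simulation of the Melanocyte Pigmentation-Proliferation
    Gene Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-circuit-perturbation style analysis of small signed
    transcription-factor circuits, built around the seven-node circuit that
    couples the melanocyte pigmentation regulators MITF and LEF1 to the
    Rb-E2F-Myc cell-cycle entry switch. Samples ensembles of kinetic
    parameter sets, integrates shifted-Hill ordinary differential equations
    to steady state from random initial conditions, z-normalises and
    clusters the resulting phenotypic states, scores pigmentation
    bimodality, simulates in-silico overexpression experiments, and
    generates synthetic single-cell expression matrices to exercise
    gene-set state-scoring end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
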