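Package: phasedyn
Title: Phase-Based Static and Dynamic Functional Connectivity with Surrogate
    and Network-Based Inference
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for phase-based analysis of multivariate neural time
    series: narrowband filtering and analytic-signal (Hilbert) phase
    extraction, Kuramoto order parameter and whole-brain metastability,
    instantaneous pairwise phase coupling and its coefficient of variation
    (dynamic functional connectivity), L1-regularized partial-correlation
    networks (static functional connectivity), multivariate phase-randomized
    Fourier surrogates with tests for genuine temporal dynamics, and
    covariate-adjusted group inference (edgewise logistic regression,
    multinomial logit, and the network-based statistic with permutation
    family-wise error control). Includes a coupled-oscillator cohort
    simulator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    nnet,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
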