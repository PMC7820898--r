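Package: plasmonet
Title: State-Machine Petri Nets from Single-Cell Gene Expression Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline from multi-replicate single-cell gene expression
    time series, as obtained by repeated sampling of Physarum polycephalum
    plasmodia, to discretized state trajectories and Waddington-landscape
    state-machine Petri nets. Covers median/geometric-mean normalization,
    technical-replicate quality control with x-fold deviation quantiles,
    hierarchical clustering with SIMPROF significance testing, trajectory
    assembly, Petri net construction with place/transition annotation,
    T-invariant (elementary cycle) enumeration, token-game simulation,
    ANDL and DOT export, classical multidimensional scaling and discretized
    expression kinetics, plus a calibrated synthetic-data generator that
    emulates the sampling design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
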