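Package: mmonet
Title: Mixed-Mode Oscillations in Heterogeneous Excitatory Neuronal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of mixed-mode oscillations (MMOs) in
    models of the pre-Botzinger complex, the medullary kernel circuit of the
    inspiratory respiratory rhythm. Implements a 100-neuron conductance-based
    network of excitatory neurons with persistent sodium (I_NaP) dependent
    bursting, heterogeneous excitability and sparse random coupling, together
    with a reduced three-neuron activity-based network amenable to fast-slow
    phase-plane analysis. Provides seeded population and connectivity
    generators, exponential-Euler and Runge-Kutta integrators, population
    burst detection and large-amplitude/small-amplitude classification,
    quantal 1:N regime summaries, parameter-sweep heat maps, nullcline and
    knee (fold) geometry, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
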