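Package: sarcolattice
Title: Spatially-Explicit Half-Sarcomere Simulation of Cooperative Muscle Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Monte Carlo simulation of calcium-regulated, cooperative force
    production in a spatially-explicit half-sarcomere. Thick and thin filaments
    are modelled as compliant chains of linear springs solved by an
    instantaneous force balance each time step, coupled to stochastic
    three-state thin-filament (regulatory unit) and strain-dependent
    cross-bridge kinetics. Configurable kinetic cooperativity (RU-RU and XB-RU
    source-target pathways) and emergent mechanical (XB-XB) cooperativity
    reproduce steady-state force-pCa relationships, rates of force development
    and ATPase turnover. Includes tidy analysis tools (three-parameter Hill
    fits, half-time rate constants) and protocol runners for parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
Config/testthat/edition: 3
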