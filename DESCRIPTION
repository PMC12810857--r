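Package: trigame
Title: Tripartite Evolutionary Game Dynamics for Healthcare Safety Supervision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and stability toolkit for the three-population replicator
    dynamics of healthcare safety-risk supervision: the public (participate in
    oversight or not), medical institutions (compliant or non-compliant care)
    and government regulators (strict or lax supervision). Provides validated
    payoff parameter sets, expected-utility and replicator vector-field
    evaluation, closed-form Jacobian analysis with eigenvalue classification of
    the eight corner equilibria, adaptive Runge-Kutta trajectory integration
    with basin-of-attraction sampling, parameter sweeps, bisection threshold
    scans, variance-based sensitivity indices, and bundled case-study
    parameterizations (tuberculosis treatment adherence, COVID-19 vaccination
    compliance, antibiotic prescription supervision). Tidyverse-native: tabular
    inputs and outputs, broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
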