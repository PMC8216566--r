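Package: mitomaint
Title: Models of Mitochondrial Maintenance in Neuronal Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of mitochondrial homeostasis ("mitostasis")
    in extended neuronal projections. Implements steady-state mean-field
    solvers for the health of motile and demand-site-stationed mitochondria
    under two exchange mechanisms -- whole-organelle interchange ("Changing
    of the Guard") and transient fusion/fission with permanently stationed
    organelles ("Space Station") -- together with a discrete stochastic
    agent-based simulator including mitophagy and local translation, and
    grid-sweep utilities for locating optimal transport parameters and
    mitophagy thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
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
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
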