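Package: bellicose
Title: Evolutionary Lattice Simulation of Overconfidence in Interstate War
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based model of territorial competition between states on a
    lattice, in which each state carries a heritable confidence factor that
    multiplies its own perceived resources when it decides whether to attack a
    neighbour. War outcomes follow a logistic conflict success function of the
    resources the two sides commit; winners annex provinces, and states whose
    capital is captured or cut off shatter into single-province successor
    states that inherit the parent's confidence factor. The package provides
    the synchronous five-phase step procedure (resource extraction, attack
    decisions, front allocation, battle resolution, structural change), an
    optional per-battle war-cost extension, a fast compiled simulation engine,
    and a replication harness for batch runs, factorial parameter sweeps, and
    war-cost and attack-threshold experiments, with tidy tibble outputs and
    ggplot2 visualisation of worlds, runs and experiment curves.
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
    generics,
    ggplot2,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
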