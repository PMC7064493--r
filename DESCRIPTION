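Package: ecoshift
Title: Scaling of Regime-Shift Duration with Ecosystem Size and Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how long ecological regime shifts take as a
    function of system size and structure. Provides seeded stochastic and
    deterministic simulators of shifting systems (a grid-based
    wolf-sheep-grass predator-prey model, a Conway-style cellular automaton
    with Moore and von Neumann neighbourhoods, a network language-adoption
    model, and a two-compartment algae-zooplankton ODE model), breakpoint
    based extraction of shift start, end and duration from simulated time
    series, log-log power-law fitting of duration against size with
    jackknife and Monte Carlo sensitivity analysis, a generator of
    empirical-style regime-shift record tables, and presets for structured
    parameter-sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
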