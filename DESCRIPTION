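Package: landspread
Title: Invasion Spread on Spatially Heterogeneous Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the spread of an invasive tree population over a
    two-dimensional landscape using a coupled reaction-diffusion system for
    adult and potential (dispersing) biomass, with optional spatially
    correlated random variation in the growth rate, crowding coefficient or
    fecundity.  Random parameter fields are built by 3x3 lattice averaging
    of i.i.d. variates, producing unit-mean, positively correlated
    landscapes.  Spread is quantified without front tracking: grid cells
    whose adult biomass exceeds a threshold are flagged as invaded, the
    mean distance of invaded cells to the source is traced through time,
    and a piecewise-linear (hinge) fit yields the asymptotic spread rate
    and the onset time of spatial spread.  A Monte Carlo driver summarises
    ensembles of random landscapes into mean and percentile curves and
    spread-rate and onset tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
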