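Package: nucspread
Title: Stochastic Simulation of Histone Modification Spreading on Nucleosome Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie next-reaction and direct
    methods) of a three-state nucleosome-array model of histone modification
    spreading. Modification enzymes (methyl- and acetyltransferases) bind at
    initiation sites, slide along the array by 1D diffusion, are recruited to
    matching marks, and may jump between chromatin-contact sites. The package
    builds the reaction network for any configuration, simulates trajectories
    and replicate ensembles with a compiled event-driven engine, and computes
    the standard summaries: time-weighted positional modification profiles,
    binned activation and relaxation dynamics, steady-state count
    distributions, seeding bistability statistics, and modification-boundary
    distributions for dual-enzyme models. Rate constants can be derived from
    physical constants (diffusion-limited association, 1D sliding, residence
    times).
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
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
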