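Package: antennafcs
Title: Protonation Kinetics and the Proton-Collecting Antenna Effect from
    Fluorescence Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying protonation dynamics at lipid membrane
    surfaces from fluorescence correlation spectroscopy (FCS). Implements the
    three-dark-state FCS correlation model with protonation, triplet and redox
    kinetics, weighted single-curve and global nonlinear least-squares fitting
    with shared photophysics parameters, extraction of protonation on/off rate
    constants and pKa values from pH series, proton-collecting-antenna geometry
    relations, a seeded synthetic-curve generator for benchmarking, and a
    kinetic Monte Carlo simulator of three-pathway proton exchange (bulk-surface
    exchange, 2D surface diffusion with capture, and direct buffer-mediated
    exchange) on nanodisc membranes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
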