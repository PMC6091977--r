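Package: cngperm
Title: Permeation Kinetics of Organic Cations Through CNG-Mimic Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of dimethylammonium (DMA)
    permeation through cyclic-nucleotide-gated (CNG) channel mimics.
    Post-processes one-dimensional free-energy profiles (minima, well
    depths, barriers, unbinding distances, block-analysis errors),
    extracts Arrhenius hopping rates, solves single-site and two-site
    single-file permeation kinetic models (stationary master equation,
    closed-form flux, half-activation constant), verifies them with exact
    Gillespie stochastic simulation, converts salt concentrations to ionic
    activities (Debye-Hueckel and Davies equations), performs global
    Michaelis-Menten fitting of normalized conductance versus activity,
    and generates synthetic profiles and electrophysiology-like datasets
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
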