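Package: fuzzyens
Title: Conformational-Ensemble Analysis for Proteins with Disordered Tails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterization of coarse-grained conformational ensembles of
    mixed-folded proteins such as galectin-3: polymer scaling-exponent fits
    and theta-point scans, Gaussian-chain end-to-end distance fitting,
    intra- and inter-molecular residue contact statistics with block-error
    estimates, Debye-formula small-angle scattering comparison against
    reference curves, and contact-based oligomer clustering. Includes seeded
    synthetic-ensemble generators (freely jointed chains, Monte Carlo
    bead-spring chains with tunable solvent quality, tethered rigid domains,
    periodic multi-molecule boxes, noisy reference scattering profiles).
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    bio3d,
    minpack.lm,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
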