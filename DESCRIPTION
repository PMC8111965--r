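Package: chromloops
Title: Whole-Nucleus Chromatin Polymer Simulation and Single-Molecule
    Localization Quantification of Chromatin Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale bead-spring polymer simulations of interphase
    chromosomes with A/B compartments and cohesin-like loops, a
    dilution-labeling / sister-chromatid-exchange model of fluorescently
    labeled chromatin fragments, synthetic 3D single-molecule localization
    microscopy (SMLM) image generation, and Voronoi/alpha-hull quantification
    (gyration radius, smoothness) used to estimate the per-megabase density
    of chromatin loops in single cells. Includes in-silico contact maps and
    compartment eigenvector analysis, plus the rank-sum and bootstrap
    statistics used to compare loop-density conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
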