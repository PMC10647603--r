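Package: catransient
Title: Calcium Transient Analysis for Single-Cell Fluorescence Imaging of
    hiPSC-Derived Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts, normalizes and quantifies single-cell calcium
    transients from fluorescence imaging of cardiomyocyte monolayers
    expressing genetically encoded calcium indicators. Starting from
    either per-frame mean-intensity tables (as exported by ImageJ Multi
    Measure) or a TIFF image stack with an integer label mask, the
    package converts frames to seconds, normalizes cell fluorescence to
    a cell-free background region, detects transients under tunable
    window/tolerance parameters with scriptable manual overrides,
    computes eleven per-transient features including a mono-exponential
    decay time constant, averages them to one value per cell, and
    compares groups of cells with one-way ANOVA and Bonferroni-corrected
    pairwise tests. A seeded synthetic-trace generator with known ground
    truth supports validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
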