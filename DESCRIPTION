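Package: fretforce
Title: Fluorescence-Force Spectroscopy Analysis of Telomeric G-Quadruplex Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule fluorescence-force
    spectroscopy of DNA G-quadruplexes: smFRET efficiency computation and
    constrained Gaussian mixture decomposition of zero-force subpopulations,
    force-ramp pulling-cycle segmentation, rupture detection and unfolding-class
    assignment, Dudko-Szabo rupture-force kinetics (rate law, distributions,
    censored maximum-likelihood fitting and force-profile reconstruction),
    extensible worm-like-chain tether mechanics for stage-driven loading
    schedules, classification of real-time vectorial folding traces, and
    synthetic-data generators that emulate the trace structure of the assay so
    every stage can be tested without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
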