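Package: antclock
Title: Circadian Rhythm Analysis of Fire Ant Clock Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tidy pipeline for detecting circadian oscillations in qPCR
    time-course data from social insect brains: delta-delta-Ct relative
    quantification against a housekeeping reference, per-colony z-scoring,
    fixed-24-h cosinor fitting by Monte-Carlo random search with a
    closed-form least-squares counterpart, permutation significance,
    additive two-way (colony x timepoint) ANOVA, and a compound
    oscillation-significance classification. Also provides pairwise global
    protein alignment with identity/similarity scoring and a 40-percent
    identity domain-conservation rule, plus seeded synthetic-data
    generators emulating the three-colony, seven-timepoint, triplicate
    study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
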