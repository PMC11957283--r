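Package: strandHI
Title: Health Index Scoring and Cohort Analysis for Stranded Marine Tetrapods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a composite Health Index (HI) in [0,1] for stranded
    seabirds, marine mammals and sea turtles from eight weighted ordinal
    necropsy and histopathology parameters, with taxon-specific maxima.
    Provides cohort-level analyses (per-group summaries, Fisher-Pearson
    skewness, HI-category binning, Kruskal-Wallis with Dunn pairwise
    comparisons against subjective health ratings, per-parameter
    contribution profiles), a latent-morbidity simulator of synthetic
    necropsy cohorts with veterinarian ratings, and CSV readers/writers
    with a fresh-carcass filter and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
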