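Package: glycoprof
Title: Whole-Serum N-Glycan Profiling, Ratio-Marker Selection and Prognostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composition-based annotation and structural
    classification of whole-serum N-glycans measured by MALDI-TOF after
    glycoblotting (benzyloxyamine tagging, sialic-acid methyl esterification,
    sodium adduct detection), construction of glycan biosynthesis networks
    with group fold-change overlays, Bonferroni-controlled differential
    screening with AUROC-based ratio-marker selection, bootstrap group
    comparisons across clinical strata, and Kaplan-Meier / Cox
    proportional-hazards prognostic analysis. Includes a synthetic
    ulcerative-colitis cohort generator so the full pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
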