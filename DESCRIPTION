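Package: cotargetr
Title: Seed-Overlap and Neighborhood miRNA Cotargeting Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterising combinatorial microRNA (miRNA) target
    regulation in 3' untranslated regions. Implements a pairwise seed-overlap
    statistic with a GC-matched randomization null, branch-length-score (BLS)
    conservation of target sites across a vertebrate species panel with a
    two-class conservation-depth split, coordinate-based classification of
    "seed overlap" and "neighborhood" cotarget sites, and downstream
    association statistics (downregulation fractions and odds ratios,
    log-additivity of combinatorial repression, haploinsufficiency
    comparisons, and hypergeometric gene-set enrichment). A synthetic-data
    generator emulates every input so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
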