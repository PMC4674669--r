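Package: chicflow
Title: Capture Hi-C Interaction Calling with a Negative Binomial Background Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Capture Hi-C experiments at restriction-fragment
    resolution: in-silico HindIII digestion and capture design (region and promoter
    bait sets with 120-bp oligo constraints), di-tag filtering and ligation-category
    classification, per-fragment interactability estimation with a left-truncated
    negative binomial noise model, a negative binomial regression background for
    calling significant cis interactions at a chosen FDR, reciprocal co-validation
    between paired capture designs via a conditional enrichment statistic, and a
    synthetic di-tag generator with known ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    MASS,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
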