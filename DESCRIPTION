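Package: proteopost
Title: Post-Analysis of Quantitative Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for the post-analysis of label-free and labeled
    quantitative proteomics data. Platform exports (wide or long delimited
    tables) are read through declarative import directives into a
    standardized four-table data object (experiments, quantitative,
    accounting, annotations) carrying an append-only operations ledger.
    Pipelined operations cover semantic filtering with a regex containment
    operator, peptide-to-protein rollup with razor and shared-peptide
    splitting, multi-channel normalization (median, linear, loess, random
    forest) with automated weighted-score selection, missing-value
    imputation within or between sample groups including iterative
    random-forest matrix completion, two-group differential expression with
    an empirical-Bayes moderated t-statistic, GSEA-style term enrichment
    with a permutation null, and the numeric tables behind every standard
    quality-control and results plot. A peptide-level simulator with full
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    dplyr,
    ggplot2,
    jsonlite,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
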