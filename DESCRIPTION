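Package: flickerstress
Title: Quantitative Analysis of Chronic Stress and Audiovisual Flicker Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for chronic-stress plus audiovisual
    flicker neurostimulation studies: composite behavioral stress-susceptibility
    scoring from directionally oriented z-scores, cell-type bulk RNA-seq
    differential expression (median-of-ratios normalization and per-gene
    negative-binomial Wald tests with explicit gene filters and thresholds),
    the "modifiable marker" sign-reversal statistic for flicker contrasts,
    hypergeometric over-representation and single-sample rank-walk enrichment,
    and 3D cell morphometry (Sholl crossings, arborization length, convex hull
    volume, dendritic spine classification and density). A synthetic-data
    module plants known behavioral shifts, fold changes, reversal fractions,
    and spine mixtures so every stage is testable without external downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
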