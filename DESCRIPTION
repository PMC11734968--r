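Package: wellnet
Title: Mixed Graphical Model Networks of Well-Being with Overlapping
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cross-sectional network-analysis pipeline for mixed
    (Gaussian and categorical) psychometric data. Estimates pairwise
    Mixed Graphical Models by nodewise l1-regularized regression with
    extended-BIC model selection, aggregates nodewise fits into a signed
    weighted network, quantifies edge stability by nonparametric
    bootstrap, computes nodewise predictability, detects overlapping
    communities by weighted clique percolation with ratio and entropy
    threshold selection against a permutation null, derives per-node
    stabilizing and communicating indices, re-estimates community
    networks at subscale resolution, and fits moderated network models.
    Includes a synthetic-data generator with planted community structure
    so every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
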