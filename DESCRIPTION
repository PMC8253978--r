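Package: reosub
Title: Relative Expression Ordering Biomarkers and Consensus NMF Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Molecular subtyping of bulk expression cohorts by consensus
    non-negative matrix factorization (Brunet multiplicative KL updates,
    cophenetic-correlation rank selection), a cumulative hypergeometric
    concordance statistic for directed differentially-expressed-gene lists,
    and rank-based within-sample classifiers built from relative expression
    ordering (REO) gene pairs: binomial stable-pair testing, subtype-specific
    reversed-pair discovery, F-score-driven greedy forward selection and a
    majority-vote classifier ensemble. Includes a multi-cohort synthetic
    expression generator (latent subtypes, gene-wise batch shifts, library
    size scaling, planted reversed pairs) so every stage is testable without
    external downloads.
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
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
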