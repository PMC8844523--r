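Package: kinfolk
Title: SNP-Based Kinship Analysis, Degree Inference, and Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for downstream analysis of SNP-based kinship estimation:
    reading and validating PLINK-style pedigree (.fam) files, computing
    expected kinship coefficients from pedigree structure via the classical
    founder recursion, translating kinship coefficients into relationship
    degrees using geometric-midpoint inference ranges, benchmarking degree
    classification with full contingency-table statistics and a reciprocal
    root-mean-square error that penalizes close-relative misclassification,
    and converting pairwise identity-by-descent segments (hap-IBD or ped-sim
    output) into kinship coefficients through a genetic map. A
    synthetic-fixture generator (multi-generation pedigrees, monotone genetic
    maps, gene-dropped IBD segments, degraded label sets) makes the whole
    pipeline testable offline and doubles as a Monte-Carlo oracle for the
    pedigree kinship recursion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    caret,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
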