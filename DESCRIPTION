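Package: amdr
Title: Aggregated Multifactor Dimensionality Reduction for Gene-Gene
    Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and aggregates multiple gene-gene (epistatic)
    interactions in case-control genotype data.  Extends multifactor
    dimensionality reduction (MDR) with calibrated predisposing
    statistics (pOR, pRR, pChi) whose null distributions are estimated
    by phenotype permutation and whose alternative distributions by
    jackknife subsampling, so that non-interacting locus pairs centre
    at 1.  Significant interactions are pooled into a continuous
    epistasis-enriched risk score evaluated by ROC/AUC, and into a
    weighted epistasis network.  Includes a penetrance-model simulator
    (Hardy-Weinberg genotypes, single-pair, genetic-heterogeneity and
    additive two-pair scenarios) and a power/type-I-error study harness,
    plus a reference implementation of original MDR (cross-validated
    accuracy, cross-validation consistency, permutation test) for
    comparison.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
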