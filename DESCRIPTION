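Package: riskdrift
Title: Polygenic Disease-Risk Differentiation Across Population Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether the polygenic genetic risk of a disease differs
    between populations by more than genetic drift can explain. Combines
    per-study genotype likelihood ratios into per-SNP effect sizes, scores
    individuals and populations by the log combined likelihood ratio, and
    tests every branch of a population phylogeny for risk differentiation
    against a resampling null built from random SNP panels matched on global
    allele frequency and functional category. Empirical branch p-values are
    corrected across the correlated tree with resampling-based q-values, and
    the number and location of independent differentiation events is inferred
    by maximum likelihood with nested chi-squared likelihood-ratio tests.
    Includes a Balding-Nichols simulator of tree-structured cohorts with
    injectable risk-shift events, Weir-Cockerham Fst comparisons, outlier
    removal, and ascertainment-controlled resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
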