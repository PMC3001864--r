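Package: crossqtl
Title: Integrative QTL, eQTL-Hotspot, Causality and Co-Expression Network
    Analysis for F2 Intercrosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for integrative genetics in F2
    intercross populations: Haley-Knott single-QTL genome scans on
    hidden-Markov genotype probabilities, permutation-based FDR for
    clinical and expression traits, trans-eQTL hotspot detection against
    Poisson and permutation nulls, likelihood-based causality model
    selection (LCMS) by AIC for locus-transcript-trait triplets, weighted
    gene co-expression network modules via soft thresholding and
    topological overlap, and matched-resampling SNP-set enrichment
    against GWAS results. Includes a seeded synthetic-cross generator
    with known ground truth so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
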