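Package: sparseherit
Title: Two-Stage SNP-Heritability Estimation with Sparse Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates SNP heritability of quantitative traits with a
    two-stage sample-splitting strategy: cross-validated elastic-net model
    selection on one random half of the cohort, followed by variance
    estimation on the independent other half under both a fixed-effect
    (high-dimensional method-of-moments) and a random-effect (single-component
    GREML) model. Includes a genotype/phenotype simulator with Hardy-Weinberg
    marginals and block linkage disequilibrium, PLINK binary and GCTA GRM
    input/output, quality-control filters (call rate, minor allele frequency,
    Hardy-Weinberg exact test), and a replicate experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
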