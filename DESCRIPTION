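Package: adipomr
Title: Polygenic-Score Mendelian Randomization for Adiponectin and
    Cardiometabolic Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-sample Mendelian randomization built on a clumping-and-
    thresholding polygenic risk score instrument. Provides base/target GWAS
    harmonization, variant- and sample-level quality control (allele
    frequency, missingness, Hardy-Weinberg exact test, imputation quality,
    heterozygosity, relatedness, principal components), LD clumping and
    p-value-threshold optimization with permutation-based empirical
    p-values, two-stage least-squares and generalized-method-of-moments
    causal estimators for continuous and binary outcomes, stratified and
    sensitivity analyses, and a synthetic-data generator with known causal
    architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
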