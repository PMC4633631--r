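Package: coherit
Title: SNP Heritability and Co-Heritability of Case-Control Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Variance-component analysis of binary (disease) traits from
    genome-wide SNP genotypes: PLINK binary fileset input/output, SNP and
    sample quality control, LD pruning and principal-component ancestry
    correction, per-SNP logistic-regression association with genomic-control
    diagnostics, genetic relationship matrices over genomic regions
    (autosomes, the extended MHC, chromosome X), univariate and bivariate
    AI-REML estimation of SNP heritability and genetic correlation with
    liability-scale transformation for ascertained case-control designs, a
    threshold-free genome-wide pairwise sharing test with an analytic
    hypergeometric null, and cross-validated linear-SVM disease prediction.
    Includes a liability-threshold simulator that generates genotypes and
    correlated binary traits with known heritability, prevalence and genetic
    correlation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
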