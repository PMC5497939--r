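Package: prsport
Title: Polygenic Risk Score Portability Across Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how polygenic risk scores (PRS) transfer
    between populations. Reads published per-SNP weight tables (single- or
    double-weighted), extracts effect-allele dosages from multi-sample VCF,
    harmonizes alleles (with palindromic-SNP filtering), computes pooled
    scaled scores, summarizes per-population distributions with quintile
    thresholds, quantifies cross-population quintile transfer, runs genotype
    PCA and PRS-PC1 correlations, compares effect-allele frequencies of
    top-weight SNPs, and validates scores against binary phenotypes by
    logistic regression. A Balding-Nichols multi-population simulator with
    analytic score moments provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
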