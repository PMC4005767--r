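Package: pairstab
Title: Stability of Exhaustive SNP-Pair Association Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the cross-validation stability of exhaustive
    bivariate (SNP-pair) association scans in case-control genome-wide
    association studies. Implements three pair statistics on 2x9 contingency
    tables: Pearson's chi-squared test, a BOOST-style log-linear
    likelihood-ratio interaction test with a Kirkwood superposition screening
    stage, and the GSS (Gain in Sensitivity and Specificity) statistic based
    on the convex hull of single-SNP ROC curves. Provides exhaustive top-k
    pair scanning with a bounded priority queue, an extension of Spearman's
    rank correlation to incomplete top-k lists, the Zero Index Crossing (ZIC)
    stability summary, a repeated stratified 2-fold cross-validation protocol
    with hub-SNP and multiple-testing analyses, a case-control genotype
    simulator with plantable main effects and epistatic pairs, and readers
    and writers for PLINK 1 binary and simple TSV genotype formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
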