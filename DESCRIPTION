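Package: asorescue
Title: Dose-Dependent Rescue Scoring of Transcriptomic Disease Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how an antisense-oligonucleotide (ASO) dosage
    perturbation rescues a transcriptomic disease signature in bulk RNA-seq
    data. Provides median-of-ratios size-factor normalization, counts per
    million, a simplified negative-binomial Wald differential-expression test
    with Benjamini-Hochberg correction, disease-signature extraction,
    cross-disorder reciprocal-dysregulation analysis (Fisher overlap and
    directional correlation of fold-changes), and rescue scoring by pooled
    log-ratio sign flips, 1-4 rank-order pattern clustering, and a principal
    component shift test. A negative-binomial count simulator with known
    ground truth emulates the genotype x treatment x dose x cell-line study
    design so every stage is testable end to end, and a small delta-delta-Ct
    utility covers relative qPCR quantification.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
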