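Package: cnvpop
Title: Population Analysis of Copy Number Variation from Windowed Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for population-scale copy number
    variant (CNV) analysis from whole-genome resequencing read depth.
    Provides a synthetic depth-track generator with planted deletions and
    duplications, a read-depth CNV caller (normalization, multi-scale
    segmentation, t-test significance, q0 repeat filtering), merging of
    per-individual calls into copy number variable regions (CNVRs) with
    deleted/conserved/duplicated classification, interval overlap against
    external CNVR catalogues, QTL tables and gene annotations, the VST
    population-differentiation statistic for selective-sweep scanning, and
    relative copy number estimation from qPCR cycle thresholds by the
    2 x 2^-ddCt method. Every stage operates on tibbles and is verified
    against brute-force oracles and simulation ground truth.
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
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
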