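Package: oppscreen
Title: Image-Based Chemical Screening for Modulators of Protein Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content chemical screens that read out
    mRNA translation through cytoplasmic incorporation of the puromycin analog
    OPP. Covers nucleus-seeded propagation segmentation of two-channel field
    images, per-well cytoplasmic intensity summaries, percent-of-DMSO plate
    normalization, triplicate hit calling with viability and reproducibility
    gates, dose-response validation across orthogonal labeling assays, and a
    proteomics stage with per-protein differential testing and a weighted
    preranked gene-set enrichment statistic. A seeded synthetic-data generator
    emulates 384-well screens (vehicle, Torin-2-like and cycloheximide-like
    control wells, planted up/down regulators, planted toxicity) and 3-vs-3
    proteomics tables so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    fgsea,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
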