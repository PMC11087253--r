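Package: mechamethyl
Title: Differential DNA Methylation Under Hyper-Physiological Mechanical
    Loading in Neo-Cartilage Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for epigenome-wide analysis of DNA-methylation
    responses to hyper-physiological mechanical loading in chondrocyte
    organoid models. Provides probe-level quality control for Infinium-style
    beta-value matrices (detection-p filtering, quantile and control-probe
    normalization, SNP-like probe flagging, blacklist removal), per-model
    differential methylation with empirical-Bayes moderated t-statistics
    implemented from the closed-form shrinkage equations, DerSimonian-Laird
    random-effects meta-analysis across organoid models, scanning for
    differentially methylated regions, chromatin-state enrichment,
    positional integration with differential expression to call
    transcriptionally active CpGs, clinical severity association, and
    RT-qPCR delta-delta-Ct statistics. A synthetic-data generator plants
    known effects so every stage is verifiable without external data.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
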