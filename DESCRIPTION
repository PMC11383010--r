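Package: enhancerclass
Title: Discovery and Characterization of Embryonic Enhancer Classes from
    CUT&RUN Histone-Mark Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering two classes of
    embryonic enhancers (H3K4me1-only versus H3K4me2-marked) from CUT&RUN
    histone-modification fragment libraries over accessible-chromatin
    regions. Builds an accessible-region catalog from two ATAC-seq peak
    sources, annotates regions against CAGE-selected transcription start
    sites, turns size-selected and spike-in-scaled fragment libraries into
    oriented per-region coverage features, classifies regions by principal
    component analysis and a support vector machine, and applies refined
    fold-enrichment class definitions. Downstream filters and statistics
    cover directional transcription at putative enhancers, DNA-methylation
    stratification and gamete overlap, motif density and CpG content,
    nearest-gene distances with rank tests, expression trajectories with
    confidence intervals, and crispant qRT-PCR delta-Ct effect estimation.
    A seeded synthetic-data module plants known region classes so every
    stage is verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stringr,
    e1071,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
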