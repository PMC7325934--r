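Package: subotu
Title: Sub-OTU Amplicon Community Analysis for Metal-Contaminated Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for fine-resolution ("sub-OTU")
    amplicon community analysis of soils with heavy-metal contamination
    gradients. Implements abundance-thresholded seed clustering of
    dereplicated reads at a 98% identity threshold, rank-aware taxonomy
    assignment with identity gates and unnamed-rank truncation,
    core-microbiome detection, Chao1 richness, negative-binomial
    differential abundance with Benjamini-Hochberg FDR control,
    Bray-Curtis ordination (PCoA, PERMANOVA, dendrograms) and canonical
    correspondence analysis against soil geochemistry (total and methyl
    mercury, carbon, nitrogen, phosphorus). Ships a synthetic amplicon
    read simulator with substitution errors and two-parent chimeras, and
    a packaged soil-geochemistry table, so the whole pipeline is testable
    end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
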