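Package: spatialith
Title: Spatial Intratumor Heterogeneity Analysis for Multi-Region Tumor Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for multi-region spatial
    immunogenomics of solid tumors. Provides chromosome- and gene-level
    copy-number event calling from segmented log2 ratios, gene-set
    signature scoring (geometric-mean and single-sample rank-based
    enrichment), simplified differential expression with hypergeometric
    over-representation, spatial similarity networks and consensus
    clustering with delta-area model selection, T-cell receptor
    repertoire statistics (clonality, Morisita-Horn overlap, sharing
    spectra, DNA/RNA activation residuals), multi-omic concordance and
    tanglegram entanglement, and mutation-based neighbor-joining
    phylogenies with bootstrap support. Ships a synthetic spatial-tumor
    generator with full ground truth so every stage is testable without
    access-restricted patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    ape,
    stats,
    utils,
    tools,
    withr,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    igraph,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
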