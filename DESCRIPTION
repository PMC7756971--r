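Package: formulanet
Title: Feature-Based Molecular Networking and Herb-Specificity Statistics
    for Multi-Herb Formula Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the metabolite-profiling workflow used in quality
    control of multi-herb formulae (e.g. Traditional Chinese Medicine
    decoctions). From aligned LC-MS feature tables, MS/MS spectra (MGF) and
    ELSD peak lists of a formula, its constituent herbs and blanks, the
    package builds a feature-based molecular network with the modified-cosine
    spectral similarity and GNPS-style mutual top-K edge filtering, computes
    herb-specificity percentages at node and cluster level, filters abundant
    components by ELSD area, annotates features by molecular-formula
    assignment and spectral-library matching with taxonomic re-ranking,
    selects abundant herb-specific markers, and extracts herb-specific
    multi-component signatures with 2D feature maps, bar chromatograms and
    ring-annotated network attribute exports. A synthetic-data generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
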