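Package: tdpquant
Title: Proteoform Quantitation for Spatially Resolved Top-Down Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates top-down proteomics search results with intact-mass
    features for label-free proteoform quantitation. Reads
    proteoform-spectrum-match (PrSM) tables from two search-engine dialects,
    aligns retention times across runs with LOESS warping, recalibrates
    per-run mass errors, clusters PrSMs into proteoform clusters (PfCs) with
    a minimum-size noise rule and five-level ambiguity classification,
    groups deconvoluted MS1 features across runs and FAIMS compensation
    voltages by chained mass and retention-time tolerances with
    deisotoping-error correction, attaches identifications to feature
    groups under explicit conflict-priority rules, and produces normalized,
    imputed proteoform abundance matrices with differential statistics and
    PCA. Also annotates MALDI intact-protein peak lists by accurate mass
    against the resulting proteoform library, and ships a ground-truthed
    synthetic-data generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
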