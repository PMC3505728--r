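Package: mirfate
Title: Evaluation of miRNA Target Predictions Against Bidirectional
    miRNA Modulation Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to evaluate seed-based miRNA target predictions against
    gene expression responses measured under bidirectional miRNA modulation
    (miRNA over-expression and anti-miR inhibition) across multiple cell
    types. Implements a 3'-UTR seed-match scanner for the 8mer, 7mer-m8 and
    7mer-1A site classes, intensity normalization with below-background
    filtering and fold-change modulation calls, a confusion-matrix
    framework (accuracy, sensitivity, specificity, FPR, FNR) stratified by
    modulation arm, cell type, conservation and seed class in both
    canonical and non-canonical orientations, attribution of modulated
    genes to direct miRNA recognition elements versus transcription-factor
    (E2F1-like) secondary regulation with a hypergeometric
    over-representation test, and dual-luciferase reporter response
    statistics. A ground-truthed synthetic-data generator emulates the
    transfection study design so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, GeneTarget
RoxygenNote: 7.3.3
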