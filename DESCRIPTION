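Package: ssapanel
Title: Submodular Selection of Genomics Assay Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chooses maximally informative, minimally redundant panels of
    genomics assay types by greedy maximization of a facility location
    objective over assay-similarity matrices built from absolute Pearson
    correlation of asinh-transformed signal tracks. Supports the "past"
    setting (select among assays already performed in a cell type) and the
    "future" setting (select assay types for a new cell type by aggregating
    correlations across reference cell types), forced inclusion of assays,
    per-assay preference weights, and cell-type selection by transposition.
    Includes three panel-quality metrics under a source/target
    cross-validation design: kernel-regression assay imputation (squared
    correlation), precision-recall evaluation of transcription-factor peak
    prediction, and annotation-based variance explained against a clustering
    stand-in segmenter; plus a synthetic multi-cell-type signal generator
    with known block-redundancy structure, bedGraph/BED/TSV readers and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
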