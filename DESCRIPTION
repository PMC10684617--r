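Package: ccsmap
Title: Mapping Dbh-Positive Cardiomyocytes of the Cardiac Conduction System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying and localising dopamine beta-hydroxylase
    (Dbh) expressing cardiomyocytes across the developing mouse heart from
    spatial (Stereo-seq style) and droplet single-cell transcriptomics, and
    for reconstructing their three-dimensional distribution from serial
    fluorescence sections. Includes spatial barcode (CID) matching with one
    mismatch, molecular identifier (MID) quality filtering and deduplication,
    DNB bin aggregation with density-based bin exclusion, stage-aware
    single-cell quality control with a developmental mitochondrial-fraction
    ceiling, marker-score cell typing, Dbh-status by cell-type contingency
    analysis, lineage-reporter (Wpre) versus real-time expression
    co-localisation summaries, rigid serial-section registration with
    flood-fill hole closure and Sobel contours, channel recoding and legacy
    VTK volume export, plus a seeded synthetic-data generator that plants
    known ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    Matrix,
    methods,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
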