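Package: mirsig
Title: miRNA qPCR Signature Classification by Diagonal Linear Discriminant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Workflow for deriving and applying small microRNA expression
    signatures of drug sensitivity from TaqMan low-density-array qPCR data.
    Processes raw cycle-threshold (Ct) tables with ceiling imputation of
    undetermined wells and endogenous-control delta-Ct normalization, screens
    probes by two-sample t-tests, fits a diagonal linear discriminant (DLDA)
    classifier with a two-score identity-line decision rule, reduces candidate
    probe sets by leave-one-out cross-validation, calibrates a selected
    signature against random same-size signatures to obtain an empirical
    adjusted p-value, clusters signature expression with heatmap and GCT/CDT
    export, filters miRNA target predictions by mirSVR-style scores, and
    simulates complete array experiments with planted signatures for
    validation of every stage.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
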