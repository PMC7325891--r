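Package: mqtrans
Title: Model-Based Quantitative Transcriptional Regulation Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects quantitative alterations of transcription-factor (TF) to
    mRNA regulatory relationships from case/control expression matrices. Each
    mRNA feature is modelled as a sparse L1-penalized linear combination of TF
    features, trained on a random split of the control samples; the absolute
    prediction residual of a sample (the mqTrans feature) measures how far it
    departs from the control-derived regulatory programme. The package
    provides readers for GEO Series Matrix files and probe/TF annotation
    resources, the per-target regression engine with hold-out quality control,
    a multi-stage screening cascade (model existence, correlation QC,
    case-vs-control elevation, false-discovery-rate restriction),
    cross-dataset confirmation by model transfer or retraining, and a
    ground-truth simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
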