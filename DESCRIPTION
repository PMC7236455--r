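Package: cellloss
Title: Cell-Loss Metric Analysis for Early Prediction of Pathologic Complete Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating a serum thymidine kinase 1 (sTK1) based
    cell-loss metric as an early predictor of pathologic complete response
    to neoadjuvant chemotherapy in breast cancer. Computes spherical tumour
    volumes and the cell-loss metric (sTK1 per unit tumour volume) at fixed
    treatment timepoints, stratifies patients into baseline-metric
    quartiles, and runs the associated inferential and predictive analyses:
    Freeman-Halton (Fisher) exact tests on 2 x k outcome tables, Wilcoxon
    comparisons, one-way ANOVA, Spearman correlation, empirical ROC curves
    with Youden cut-off selection, and reconstruction of integer confusion
    matrices from rounded printed predictive values. Includes a calibrated
    synthetic-cohort generator so that every pipeline stage is testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
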