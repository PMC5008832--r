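Package: beprog
Title: Biomarker Discovery and Validation for Barrett's Esophagus
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cross-dataset meta-analysis pipeline for discovering and
    validating expression biomarkers that predict malignant progression
    of Barrett's esophagus. Implements frozen-reference quantile
    normalization, empirical-Bayes moderated differential expression
    with a negative-control-calibrated log-odds (B-statistic) threshold,
    expression-barcode binarization with dataset and group consistency
    filtering, hypergeometric gene-set enrichment, guilt-by-association
    network prioritization, and the validation statistics used on
    clinical cohorts: 2^-ddCt relative qPCR quantification, qPCR
    standard curves, rank-sum and chi-squared tests, and follow-up
    summaries. Ships a synthetic multi-dataset cohort generator with
    planted ground truth so the whole discovery funnel is testable end
    to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), limma, withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
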