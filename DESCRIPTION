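Package: diaphmon
Title: Continuous Diaphragm Ultrasound Monitoring During Weaning Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of continuous diaphragm-excursion monitoring
    during spontaneous breathing trials in mechanically ventilated patients.
    Provides a synthetic generator for multichannel respiratory waveforms
    (diaphragm displacement, esophageal/gastric/transdiaphragmatic pressure,
    airflow) with ground truth; breath segmentation by zero crossings of the
    transdiaphragmatic pressure signal with automated artifact rejection;
    per-breath metrics (excursion, peak contraction velocity, peak Pdi,
    pressure-time product, tidal volume) and trimmed per-minute summaries;
    method-comparison statistics (Bland-Altman, Passing-Bablok with CUSUM
    linearity, Spearman); weaning-failure prediction (ROC, Youden cutoffs,
    stratified bootstrap, DeLong AUC comparison, exact binomial intervals);
    and repeated-measures correlation for within-patient pressure-excursion
    coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
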