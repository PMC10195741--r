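Package: membias
Title: Emotional Memory Bias Scoring and Mediation Analysis for
    Biofeedback Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing emotional memory outcomes of randomized
    heart-rate-variability biofeedback trials. Scores recognition memory
    (hits, false alarms, corrected recognition, Remember/Know) and
    dual-coded free recall, estimates inter-rater reliability with
    Krippendorff's alpha and a bootstrap confidence interval, builds a
    z-score composite measuring positive > negative memory bias, fits
    single-mediator mediation models with covariates and
    percentile-bootstrap inference, and runs mixed-design factorial
    ANOVAs with partial eta-squared. A synthetic cohort generator with
    known ground-truth mediation paths supports calibration and
    end-to-end testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
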