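Package: bradyglucose
Title: Bradycardia Detection and Glucose-Linked Risk Analysis from RR and CGM Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking continuous glucose monitoring (CGM) to
    bradycardia in beat-to-beat RR-interval streams. Detects bradycardia
    episodes (runs of more than four consecutive beats below 45 bpm), extracts
    short-term (5-minute) heart-rate-variability features in the time,
    frequency and nonlinear domains, assigns personalized relative glucose
    tertiles, quantifies tertile enrichment of bradycardia with time-banded
    bootstrap Fisher statistics and bootstrap Wilcoxon feature tests, and
    evaluates a balanced bootstrap Random-Forest forecaster of pre-bradycardia
    risk windows. Includes a synthetic multi-patient cohort generator with
    circadian glucose and heart-rate structure and injected episodes with
    known ground truth, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
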