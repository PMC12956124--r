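Package: pshkit
Title: Automated Detection and Quantification of Paroxysmal Sympathetic
    Hyperactivity from Continuous Vital-Sign Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying paroxysmal sympathetic hyperactivity (PSH)
    in continuously monitored brain-injured patients from 0.5 Hz vital-sign
    trend data (heart rate, respiratory rate, systolic blood pressure).
    Implements an hourly high-resolution Clinical Feature Scale (hrCFS, 0-9),
    a rule-based expert-system episode detector (sliding-window heart-rate
    minimum/median/variance rules with 2-of-3 voting and per-sample
    max-fusion), a support-vector-machine episode detector over rolling-window
    summary features, an episode burden score with 12-hour trend summaries,
    range-based (interval) precision and recall for evaluating detected
    against annotated episodes, and a synthetic vital-sign simulator with
    ground-truth episodes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
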