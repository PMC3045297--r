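Package: psbridge
Title: Propensity-Score-Matched Indirect Comparison of Antipsychotic Trial Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level indirect comparison of two placebo-controlled
    antipsychotic trial programs using propensity score methodology:
    hierarchical 1-to-many greedy caliper matching with a placebo-poolability
    check, last-observation-carried-forward endpoint construction with
    baseline-adjusted analysis-of-covariance contrasts for PANSS, CGI-S and
    weight, responder analysis, and clamped placebo-adjusted adverse-event
    rate differentials with incidence and differential thresholds. Includes a
    calibrated six-trial synthetic cohort generator so the full pipeline can
    be exercised and validated without access to proprietary trial databases,
    plus fixtures of the published summary tables for exact reproduction of
    every derivable printed cell.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
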