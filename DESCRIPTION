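Package: treatthresh
Title: Physician Treatment-Risk Thresholds from Ordinal Recommendations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates an individual physician's treatment-risk threshold
    from ordinal, uncertainty-bearing treatment recommendations. A
    proportional-odds (cumulative logit) model is fitted per physician
    against each case's calculated disease risk, and the threshold is the
    risk at which a "Yes" and a "No" recommendation are equally likely.
    Includes simulation of synthetic ocular-hypertension case cohorts from
    truncated-normal population summaries, a pluggable linear-predictor
    risk model, a proportional-odds generator of physician response panels
    for parameter-recovery studies, per-fit diagnostics (Nagelkerke
    pseudo-R-squared, concordance index), and population-level beta
    maximum-likelihood summaries of the threshold distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
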