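Package: vetemulate
Title: Target Trial Emulation for Veterinary Electronic Health Record Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for emulating randomised trials from
    observational veterinary cohort data, built around a canine
    acute-diarrhoea exemplar. Provides eligibility filtering against a
    target-trial protocol, stabilised inverse-probability-of-treatment
    weighting with missing-indicator covariate encoding and balance-driven
    interaction selection, standardised-mean-difference balance diagnostics,
    inverse-probability-weighted risk differences with robust (sandwich)
    standard errors, unadjusted and IP-weighted discrete-time
    time-to-event analysis with bootstrap confidence intervals, an
    equivalence-trial sample-size design, and a synthetic cohort generator
    with known counterfactual truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
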