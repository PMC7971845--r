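Package: sprintcea
Title: Cost-Effectiveness Microsimulation of Intensive Systolic Blood
    Pressure Control
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the population reach and lifetime
    cost-effectiveness of intensive (<120 mm Hg) versus standard
    (<140 mm Hg) systolic blood-pressure treatment goals in a
    survey-style adult population. Provides a synthetic survey
    population generator with a Gaussian-copula joint covariate
    structure and survey-weighted estimation, a multistep
    SPRINT-eligibility screen (Framingham general cardiovascular risk,
    CKD-EPI kidney function, sequential criterion funnel), a 9-state
    annual-cycle individual-level cardiovascular microsimulation with
    common random numbers across treatment arms, payer-perspective
    costing and utility accrual with discounting, and full
    cost-effectiveness analytics: ICERs, national event scaling,
    one-way (tornado) sensitivity analysis, probabilistic sensitivity
    analysis, acceptability curves, and subgroup analyses.
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
    optparse
Config/testthat/edition: 3
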