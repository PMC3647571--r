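Package: ndrpath
Title: Dynamic Time-Path Equations for Cardiovascular Risk Factors in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the year-by-year evolution of five
    cardiovascular risk factors (HbA1c, systolic blood pressure, BMI,
    total-to-HDL cholesterol ratio and LDL cholesterol) after a diagnosis of
    type 2 diabetes.  Ships a published coefficient set estimated on the
    Swedish National Diabetes Register, a deterministic trajectory engine for
    first-order dynamic risk-factor equations (short-term and long-term
    covariate effects, steady states), a Blundell-Bond system GMM estimator
    for fitting such equations to unbalanced patient panels (with Windmeijer-
    corrected two-step standard errors, Hansen overidentification and
    Arellano-Bond serial-correlation diagnostics), a seeded generator of
    register-like synthetic cohorts, and machinery for temporal external
    validation (observed-on-predicted regression and RMSE model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
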