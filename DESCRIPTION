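Package: bmitraject
Title: BMI Trajectories Before and After Type 2 Diabetes Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating longitudinal BMI trajectories around the
    diagnosis of type 2 diabetes from electronic-medical-record style data.
    Builds analysis cohorts by anchor-measurement windowing and eligibility
    filtering, codes time-varying drug-regimen and HbA1c-change exposures
    from dispensing and laboratory records, and fits linear mixed-effects
    models with per-individual random intercepts and slopes and a
    continuous-time spatial-power residual correlation by REML, including
    BLUP-based individual annual BMI-change rates, studentised-residual
    outlier screening with refit, and seven-level weight-change
    categorisation. A synthetic EMR generator with a truth ledger supports
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    withr
Config/testthat/edition: 3
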