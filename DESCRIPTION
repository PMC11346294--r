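Package: nodulegrowth
Title: Growth Dynamics and Malignancy Classification of Screen-Detected
    Lung Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal CT volumetry of pulmonary
    nodules detected in lung cancer screening. Fits the von Bertalanffy
    scaling law dV/dt = alpha * V^beta to per-nodule volume series,
    categorizes growth patterns (decelerated, linear, subexponential,
    exponential, accelerated) from the fitted exponent, computes linear and
    exponential growth rates and two volume-doubling-time estimators
    (modified Schwartz and scaling-law based), runs a Monte-Carlo
    sensitivity analysis of the growth exponent against multiplicative
    volumetry errors, and evaluates candidate benign-versus-malignant
    discriminators by ROC/AUC, including a stepwise multivariable score
    combining growth rate with CT morphology. A calibrated synthetic cohort
    generator emulates the statistical structure of a screening cohort so
    that every stage of the pipeline is testable without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
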