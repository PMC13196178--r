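Package: predsize
Title: Simulation-Based Sample Size Calculations for Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A general, simulation-based framework for choosing the sample size
    of a study that develops or updates a clinical prediction model. Given a
    case-mix distribution for the target population, a reference ("true")
    logistic model, and a planned model-development strategy, the package
    anticipates posterior distributions of individual risk predictions and of
    performance-degradation metrics (calibration slope and intercept,
    c-statistic, MAPE/RMSPE, net benefit and the relative value of sample
    information, prediction instability) at candidate sample sizes, and reports
    assurance probabilities that chosen performance criteria will be met.
    Includes a fast Fisher unit-information approximation for unpenalised and
    Bayesian penalised logistic regression via Metropolis-Hastings with ridge
    or lasso shrinkage priors, and closed-form starter sample-size criteria
    (calibration-slope shrinkage and overall-risk precision) with a
    c-statistic to Cox-Snell R-squared conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    splines,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
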