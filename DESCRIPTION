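Package: shockcea
Title: Cost-Utility Modelling of Revascularisation Strategies in
    Infarct-Related Cardiogenic Shock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility pipeline comparing culprit-lesion-only
    percutaneous coronary intervention (CO-PCI) against immediate multivessel PCI
    (MV-PCI) in acute myocardial infarction complicated by cardiogenic shock.
    Provides a calibrated synthetic patient-level trial generator, mutually
    exclusive health-state classification, within-trial costing with
    friction-cost productivity losses and conditional-mean imputation,
    estimation of decision-tree probabilities, parametric survival
    extrapolation with information-criterion model selection and random-effect
    utility/cost panel models, a one-year decision tree chained to a lifelong
    monthly-cycle Markov cohort model with life-table proportional mortality,
    and decision metrics: ICER, net monetary benefit, cost-effectiveness
    acceptability curves, probabilistic sensitivity analysis and subgroup
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    flexsurv,
    lme4,
    survival,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
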