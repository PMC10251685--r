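Package: nbreg
Title: Net-Benefit Regression for Moderators of Cost-Effectiveness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for net-benefit regression analysis of randomized trials
    with symptom-free-day effectiveness outcomes. Converts Beck Anxiety
    Inventory assessments into anxiety-free days, builds individual
    net-benefits over a willingness-to-pay grid, fits ordinary
    least-squares net-benefit regressions on multiply imputed data
    (bootstrap-EM imputation with Rubin's-rules pooling), screens baseline
    covariates as confounders and treatment-effect moderators, constructs
    plain and moderator-stratified cost-effectiveness acceptability curves,
    and runs a regression-diagnostics battery aggregated across imputed
    datasets. Includes a seeded synthetic-trial generator with known
    cost and effectiveness structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
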