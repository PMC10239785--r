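Package: glaucodose
Title: Alcohol Dose-Response, Gene-Environment Interaction and Mendelian
    Randomization Analyses for Glaucoma-Related Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying habitual alcohol intake from
    beverage-frequency questionnaires, deriving intraocular pressure, macular
    OCT and glaucoma phenotypes from raw ocular measurements and diagnosis
    records, and relating exposure to outcome: categorical and per-SD
    regression contrasts, quintile trend tests, restricted cubic spline
    dose-response models with AIC knot selection, polygenic-score
    gene-environment interaction tests, and a complete two-sample Mendelian
    randomization suite (inverse-variance weighted, MR-Egger, weighted median,
    weighted mode, MR-PRESSO and multivariable MR) with heterogeneity and
    pleiotropy diagnostics. A synthetic-data module generates cohorts and GWAS
    summary statistics with the statistical structure these analyses assume,
    so every stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
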