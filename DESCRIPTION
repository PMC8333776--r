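Package: preventyll
Title: Preventable Cancer Burden and Cost Modelling for Population-Wide
    Vitamin D Supplementation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic modelling of cancer deaths and years of life
    lost (YLL) preventable by population-wide vitamin D supplementation,
    with the associated cost and savings accounting. Implements
    inverse-variance fixed-effect and DerSimonian-Laird random-effects
    pooling of trial-level risk ratios, life-table YLL computation via
    the age-interval midpoint rule, a proportional mortality-reduction
    impact model, supplementation-cost versus end-of-life-care-savings
    accounting with cost-per-life-year ratios, a deterministic
    sensitivity-scenario grid, and a calibrated synthetic generator for
    age/sex-stratified mortality and life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
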