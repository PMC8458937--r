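Package: mrmcea
Title: Cost-Effectiveness Modelling of MR-Mammography Screening in Dense Breasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model comparing biennial breast-cancer screening
    with MR-mammography (MRM) against x-ray mammography (XM) in women with
    extremely dense breast tissue. A per-round diagnostic decision tree feeds an
    annual-cycle Markov cohort model run over a 20-year horizon with discounted
    costs and quality-adjusted life years. Provides incremental
    cost-effectiveness ratios and net monetary benefit, deterministic (tornado,
    two-way, break-even) and probabilistic (Monte Carlo with
    cost-effectiveness acceptability curves) sensitivity analyses, and
    deterministic grid-search calibration of the transition-structure
    parameters the published evidence leaves implicit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
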