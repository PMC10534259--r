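Package: sbtaxsim
Title: Cost-Utility Simulation of Sweetened-Beverage Taxation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A comparative cost-utility modelling pipeline for specific
    (per-litre) excise taxes on sweetened beverages. Converts a tax design
    into price changes via pass-through, applies an own- and cross-price
    elasticity matrix to per-age-band beverage consumption, translates the
    resulting change in daily energy intake into body-weight and BMI shifts
    with a steady-state energy-balance factor, and propagates the BMI shift
    through a proportional multi-state life-table Markov model of nine
    obesity-related diseases via potential impact fractions. Outputs
    incremental health-adjusted life years, healthcare cost offsets,
    policy implementation costs, taxation revenue, and incremental
    cost-effectiveness ratios with dominance classification, with
    probabilistic sensitivity analysis by Monte Carlo simulation. A
    synthetic-data module generates internally consistent inputs (closed
    cohort aged 2-100, beverage consumption by age band, illness-death
    disease rates) so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
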