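Package: ssbtax
Title: Simulated Health Impact of Sugar-Sweetened Beverage Taxation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation pipeline linking a sugar-sweetened beverage (SSB)
    excise tax to body weight, obesity and diagnosed type-2 diabetes in an
    adult population. Generates a synthetic survey-like adult population with
    zero-inflated log-normal SSB consumption, applies socioeconomic-status
    specific purchase reductions, integrates the Chow-Hall dynamic
    energy-balance model of individual weight change, classifies WHO BMI
    categories with survey weights, and projects diagnosed diabetes with a
    multi-cohort Markov state-transition model under counterfactual
    relative-risk scaling. Includes a comparative risk assessment
    sensitivity analysis using meta-analytic BMI-per-serving coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
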