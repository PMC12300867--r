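Package: dietmarkov
Title: Markov Cohort Modelling of Dietary Interventions on Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic Markov cohort simulation of the medical and economic
    impact of increased yogurt intake on type 2 diabetes (T2D) in Japan. Builds
    annual transition probabilities from published sex- and age-stratified
    incidence, prevalence and mortality rates together with a log-linear
    dose-response relative risk per 50 g/day of intake, traces a closed cohort
    over a 10-year horizon, accrues discounted outpatient healthcare
    expenditures on the chronic-disease state, compares intake scenarios
    against a baseline, and runs deterministic one-way (tornado) sensitivity
    analyses over parameter confidence intervals. Ships the Japan-2019
    parameter tables as a built-in fixture, reads and writes user-supplied
    parameter sets (CSV plus JSON/YAML config), generates synthetic parameter
    sets with the same statistical structure, and provides an individual-level
    Monte Carlo microsimulation oracle for validating the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
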