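Package: neopkpd
Title: Neonatal Beta-Lactam Population PK Simulation, Target Attainment and
    Model Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based evaluation of intravenous amoxicillin and
    benzylpenicillin dosing regimens in (pre)term neonates during the first
    48 hours of life. Provides closed-form one- and two-compartment infusion
    population pharmacokinetic models with allometric birth-weight scaling and
    postmenstrual/postnatal-age clearance maturation, a gestational-age
    stratified virtual neonatal population generator, formulary dosing-regimen
    resolution (intermittent, gestational-age based, and continuous infusion
    with loading dose), probability of target attainment (%fT>MIC) and
    toxicity-duration analyses with protein-binding sensitivity sweeps, and an
    external model-evaluation battery (prediction-error metrics,
    prediction-corrected visual predictive checks, normalized prediction
    distribution errors, MAP empirical-Bayes estimation) together with a
    sparse therapeutic-drug-monitoring style synthetic study generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    deSolve,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
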