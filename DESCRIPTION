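Package: cvrmdash
Title: Headless Decision-Support Engine for Cardiovascular Risk Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable, headless decision-support engine for cardiovascular
    risk management (CVRM). Assembles typed risk profiles from four
    EHR-style data streams (questionnaire, measurements, laboratory
    results, medication register), triages each patient to one of four
    10-year cardiovascular risk models (HEART score, SMART, ADVANCE,
    Elderly) via a configurable business-rule decision tree, evaluates
    Cox-form risk equations from declarative model definitions, generates
    guideline-target treatment suggestions with red/green status flags,
    computes counterfactual risk under on/off intervention scenarios,
    performs mean imputation with provenance tracking, audits data
    completeness and accuracy, and emits a structured dashboard payload
    with print and copy-to-consult renderings. Ships a synthetic cohort
    generator so the full pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
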