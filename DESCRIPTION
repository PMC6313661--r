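Package: mcdaid
Title: Preference-Sensitive Multi-Criteria Decision Support for Treatment Choices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A value-based compensatory multi-criteria decision analysis
    (MCDA) engine for patient decision support. Options are scored by
    expected value, integrating per-criterion 0-1 performance ratings with
    person-supplied importance weightings; a GRADE certainty-of-evidence
    mapping (very low/low/moderate/high onto 0.1/0.4/0.7/1.0) yields
    certainty-adjusted scores presented alongside unadjusted ones.
    Preference sensitivity is quantified by closed-form one-way weight
    flip thresholds and by Dirichlet simulation of the share of informed
    patients preferring each option, with a quantitative
    strong/weak/equipoise classification. Ships a worked decision model
    for transfemoral TAVI versus surgical aortic valve replacement (SAVR)
    in severe symptomatic aortic stenosis, a versioned JSON model-document
    format, a plain-text one-screen report, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
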