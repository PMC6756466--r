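Package: strokepathsim
Title: Stroke Thrombolysis Pathway Simulation and Clinical Decision Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation of the emergency stroke pathway from
    onset to thrombolysis, an onset-to-treatment-time dependent model of
    additional disability-free outcomes, and a random-forest model of
    per-hospital treatment decisions that can transplant decision-making
    between hospitals. Includes a synthetic multi-hospital audit-cohort
    generator emulating national stroke audit extracts, what-if scenario
    analysis of pathway improvements, and bootstrap validation of the
    simulator against observed thrombolysis use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
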