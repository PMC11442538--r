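Package: carecost
Title: Societal Cost of Informal Care from Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A bottom-up, prevalence-based costing pipeline for informal
    (unpaid family/friend) care from caregiver survey microdata. Values
    care time under the opportunity-cost and proxy-good methods, computes
    productivity losses (prolonged and temporary work cessation, reduced
    work hours, presenteeism) under the human-capital and friction-cost
    approaches, aggregates to survey-weighted national totals with gender
    stratification and macro context metrics, and runs deterministic
    one-way sensitivity scenarios. Ships a calibrated synthetic survey
    generator so the full pipeline is testable without restricted
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
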