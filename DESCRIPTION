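Package: sicklecea
Title: Cost-Effectiveness Modelling of a Durable Cure for Sickle Cell Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime Markov cohort model comparing a hypothetical
    single-administration durable (cell or gene) therapy for sickle cell
    disease against standard of care from the US healthcare sector
    perspective. Severity transitions follow gender-specific ordered-logit
    regressions on age, annual direct costs follow gamma log-link
    regressions, and mortality comes from life tables (user-supplied or
    calibrated Gompertz-Makeham stand-ins). Includes deterministic and
    probabilistic sensitivity analysis, cost-effectiveness acceptability
    curves and frontier, expected value of perfect information, threshold
    pricing, cure-waning scenarios, and a synthetic patient-year claims
    generator with parameter-recovery refitting of both regressions.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
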