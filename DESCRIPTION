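Package: wardflex
Title: Stochastic Simulation and Economic Evaluation of Hospital Nurse
    Staffing Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.invalid")
Description: Monte-Carlo simulation of hospital inpatient units under
    alternative baseline nurse rostering plans (flexible, standard,
    resilient) with flexible responses to staffing shortfalls: floating
    staff within specialty groups and hiring temporary bank or agency
    staff under configurable availability scenarios.  Includes a
    synthetic hospital generator calibrated to realistic demand-shape
    statistics, an acuity-based demand model, a shift-level staffing
    engine with a shortfall trigger tolerance, and a health-economic
    layer producing exposure summaries, deaths and bed-day effects,
    numbers needed to treat or harm, and net cost per life saved,
    together with a parameter-perturbation sensitivity grid.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
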