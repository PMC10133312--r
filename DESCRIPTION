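Package: curablate
Title: Statistical Cure and Years of Life Lost After Ablation of
    Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits flexible parametric (spline-based) non-mixture cure models
    for disease-free survival on the relative-survival scale, with background
    mortality taken from national life tables. Provides cure-fraction and
    time-to-cure prediction, loss in expectation of life (years of life lost)
    via life-table expected survival, a published-coefficient bedside
    calculator for patients with hepatocellular carcinoma treated by
    radiofrequency or microwave ablation, classical Kaplan-Meier utilities
    (including reverse Kaplan-Meier follow-up and a cure-plausibility plateau
    check), and a seeded synthetic-cohort generator for end-to-end validation
    of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
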