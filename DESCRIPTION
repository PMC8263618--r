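Package: pelime
Title: Machine-Learning and Genetic Dissection of Pulmonary Embolism Risk
    in Venous Thrombosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for discovering molecular and
    genetic signals that separate pulmonary embolism (PE) from isolated deep
    vein thrombosis (DVT) in venous thromboembolism cohorts profiled with
    antibody suspension bead arrays. Provides edited-nearest-neighbours
    cohort homogenisation, ADASYN minority oversampling, an iteratively
    balanced feed-forward neural network classifier trained by
    backpropagation, LIME local linear surrogates yielding a per-subject
    quantitative PE predictor, a quantitative-trait association scan of that
    predictor over imputed genotype dosages, recessive-model case-control
    genetics (Cochran-Armitage trend, Fisher exact, age/sex-adjusted
    logistic regression with separation detection), and staged rare-variant
    prioritization. A seeded synthetic-cohort generator reproduces the
    statistical structure the analysis assumes so every stage is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
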