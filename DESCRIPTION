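Package: extantr
Title: Extinction-Risk Modelling and Persistence Extrapolation for
    Rare-Species Occurrence Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits binomial logistic extinction models to repeated-survey
    records of rare-species populations (covariates: log initial population
    size, years between surveys, elevation), selects the model by BIC over
    all candidate term sets obeying marginality, and extrapolates the number
    of still-extant populations in an occurrence database by summing
    predicted survival probabilities. Prediction uncertainty comes from an
    empirical coefficient bootstrap: resurvey records are resampled with
    replacement, the model is refit, and each coefficient draw is propagated
    through the database predictions to percentile intervals. Includes a
    synthetic-data generator that emulates the covariate structure of
    resurvey data sets and agency occurrence databases so the whole pipeline
    is testable without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
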