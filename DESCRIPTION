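Package: phenolmm
Title: Smartwatch Digital Phenotypes and Psychopathology Dimensions via
    Linear Mixed-Effects Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline relating passively collected smartwatch
    sensor streams to monthly symptom-dimension ratings in longitudinal
    psychiatric cohorts. Derives per-window digital phenotypes (short-time
    energy of accelerometer and gyroscope norms, normal-to-normal interval
    counts, RMSSD), daily sleep:wake and step summaries, and 20 monthly
    phenotype aggregates with recording-completeness filters; fits linear
    mixed-effects models by maximum likelihood with random intercepts,
    AR(1) residual correlation, and random slopes, with Satterthwaite
    degrees of freedom, marginal pseudo-R2 and Cohen f2 effect sizes, and
    boundary-corrected (half-half chi-square mixture) likelihood-ratio
    tests; and drives a 3-step model-selection procedure per
    phenotype-dimension pair including covariate screening and
    confounder-interaction models. A seeded synthetic-cohort generator
    with known ground truth makes every stage testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
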