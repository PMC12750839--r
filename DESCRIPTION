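Package: coda24
Title: Compositional Analysis of 24-Hour Movement Behaviours and
    Adolescent Wellbeing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compositional data analysis (CoDA) of 24-hour movement
    behaviour compositions (sleep, sedentary time, light physical
    activity, moderate-to-vigorous physical activity) in relation to
    domain-specific adolescent wellbeing measured with the 20-item
    EPOCH instrument.  Provides simplex arithmetic (closure,
    perturbation, compositional geometric means, variation matrices),
    isometric log-ratio pivot coordinates with part rotation,
    accelerometer intensity classification and valid-day filtering,
    EPOCH domain scoring, covariate- and cluster-adjusted compositional
    linear regression, a pairwise time-reallocation (isotemporal
    substitution) engine, and a fully seeded synthetic-cohort generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    sandwich,
    lmtest,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
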