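Package: adescale
Title: Age-Dependent Exponent Allometric Scaling of Therapeutic Protein
    Clearance in Children
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts pediatric clearance of therapeutic proteins
    (monoclonal antibodies, polyclonal immunoglobulins, and non-antibody
    proteins) from adult clearance by weight-based allometric scaling with
    age-dependent exponents (1.2 preterm and 1.1 term neonates, 1.0 for
    infants and toddlers, 0.9 for preschool children, 0.75 above five
    years).  Ships a curated dataset of 75 published pediatric clearance
    observations for 29 therapeutic proteins with percent-prediction-error
    evaluation and accuracy binning at the 30% and 50% thresholds, a
    median weight-for-age reference for weight imputation, and a
    synthetic-cohort simulator with log-linear allometric exponent
    recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
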