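Package: baboonbonds
Title: Male-Male Social Bonds, Coalitionary Support and Reproductive
    Success in Guinea Baboons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for analysing male-male sociality in wild
    Guinea baboons (Papio papio): ingestion and validation of behavioural
    observation tables, the dyadic composite sociality index (DSI) with
    bond-strength and strong-bond metrics, coalition rates, daily
    reproductive-unit composition from female-male interactions,
    microsatellite locus QC and trio-likelihood paternity assignment with
    simulation-based confidence, and Poisson/beta generalized linear mixed
    models with offsets, overdispersion correction, likelihood-ratio tests
    and parametric bootstrap intervals. A synthetic-data generator with a
    ground-truth table emulates the field study so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    lme4,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
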