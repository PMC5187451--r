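Package: jitai
Title: Just-in-Time Adaptive Intervention Engine for Smoking Cessation EMA Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable engine for a smartphone-delivered just-in-time adaptive
    intervention (JITAI) for smoking cessation built on ecological momentary
    assessment (EMA). Implements the prompt scheduler (daily diary, random
    sampling within waking hours, event-contingent follow-ups with a 60-second
    answer window and a per-day smoking-occasion sampling cap), the four-level
    tailored-message decision algorithm with trigger prioritisation and a
    pluggable lapse-risk estimator, on-demand content logging, compensation
    tiers, and carbon-monoxide-verified point-prevalence abstinence
    classification. A synthetic-cohort simulator with latent AR(1)
    urge/stress/affect dynamics and a logistic lapse hazard generates event
    logs and visit tables so the whole pipeline is exercisable without
    participant data, and a feasibility-metrics layer summarises compliance,
    message delivery, feature use and abstinence.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
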