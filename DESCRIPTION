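Package: wmtraj
Title: Time-Sensitive Modeling of Working-Memory Performance Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models trial-by-trial accuracy on a spatial-span working-memory
    task as a nonlinear mixed-effects learning curve with participant-level
    initial accuracy, rate of change (a time constant), and asymptotic
    accuracy, fit to fully disaggregated per-click Bernoulli outcomes.
    Extracted participant estimates feed an individual-differences layer
    relating trajectory components to fluid-intelligence scores via
    bootstrap correlations, default-prior Bayes factors on the log-base-3
    scale, joint and robust regression, and Fisher-z power analytics.
    Includes a synthetic-cohort generator mirroring the model's generative
    assumptions, chance-performance screening with exact binomial tests,
    and a reproducible file-based pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    coda,
    jsonlite,
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
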