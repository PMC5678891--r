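Package: vo2kinetics
Title: Multimodel Inference for Post-Exercise Oxygen Uptake Recovery Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models breath-by-breath oxygen uptake (VO2) kinetics recorded
    around 6-minute walk tests, with a focus on the post-exercise recovery
    phase in chronic obstructive pulmonary disease (COPD). Provides three
    combined exercise + recovery curve families (log-logistic, Weibull 1,
    Weibull 2), per-patient nonlinear least-squares fitting with analytic
    gradients, three cohort summarization strategies (nonlinear mixed
    effects, two-step random-effects meta-analysis, weighted regression),
    Akaike-weight model averaging with a conservative unconditional
    variance, stage contrasts, a synthetic-cohort generator, and an
    end-to-end reporting pipeline.
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
    metafor,
    minpack.lm,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
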