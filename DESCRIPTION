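Package: rbdprt
Title: Reward Behavior Disengagement Analysis for the Probabilistic Reward Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying reward task engagement from Probabilistic
    Reward Task (PRT) behavior. Computes classical signal-detection measures
    (response bias log b, discriminability log d) per block, scores Reward
    Behavior Disengagement (RBD) as the expected-value shortfall of observed
    responding relative to the reward-maximizing ideal observer, derives an
    objective engaged/disengaged cutoff by univariate quadratic discriminant
    analysis against healthy controls, and tests whether the resulting
    classification moderates longitudinal treatment response in a
    repeated-measures linear mixed model with a spatial-power residual
    covariance. Includes a parametric cohort simulator emulating a
    two-phenotype depressed sample with healthy controls, and an end-to-end
    pipeline chaining simulation, scoring, classification and outcome
    modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
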