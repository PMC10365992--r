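Package: fitmax
Title: Fitness-Maximizing Efficient Sensory Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying efficient sensory coding when the objective is
    the organism's fitness rather than raw information transmission. Implements
    escort-distribution (power-law) response functions and quantized-code loss
    functionals over arbitrary stimulus priors, a Bayesian encoding-decoding
    observer with closed-form bias and variance approximations and a
    two-alternative choice rule with lapse and side bias, numerical
    Fisher-information allocation optimizers (including categorization
    thresholds for non-monotonic reward maps and drift-diffusion reaction-time
    costs), a hierarchical Bayesian fitter for binary choice data, seeded
    generators emulating staircase-controlled orientation discrimination and
    estimation experiments, and a small capacity-constrained stochastic
    (variational information bottleneck) network experiment.
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
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    coda,
    jsonlite,
    rjags,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
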