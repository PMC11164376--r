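Package: tonerace
Title: Longitudinal Inverse-Gaussian Race Models for Speech Category Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing multi-session non-native
    speech category learning experiments. Implements a multi-alternative
    drift-diffusion (inverse-Gaussian race) model with participant- and
    block-varying drift rates and decision boundaries, fitted by Markov
    chain Monte Carlo with B-spline smoothing over training blocks;
    behavioural scoring (reaction-time trimming, block accuracy, learner
    classification, operation-span scoring, maintenance and generalization
    scores); random-intercept linear mixed models linking working-memory
    capacity to accuracy and decision parameters; and a fully seeded
    synthetic-cohort generator that emulates a 4-category, 3-session
    Mandarin tone training design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    stats,
    splines,
    jsonlite,
    yaml,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
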