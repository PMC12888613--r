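Package: traitlearn
Title: Generative Models of Social Trait Learning with Hierarchical
    Bayesian Fitting and Cross-Validated Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a family of eight generative models of how people
    estimate and learn other people's personality traits from trial-by-trial
    feedback: no-learning reference-point models, coarse-granularity
    (Big Five factor level) delta-rule models, and fine-granularity models
    that generalize feedback across traits through a trait-trait similarity
    matrix. Provides hierarchical Bayesian estimation of condition-level
    parameters with posterior contrasts and shortest probability intervals,
    leave-one-participant-out cross-validated model comparison scored by
    mean squared error with a 2xSE decision rule, model-free prediction-error
    summaries and trial trends, and a synthetic-study generator that
    emulates the trait-learning task (six profiles, 40 traits, 8-point
    ratings) with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    coda,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
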