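Package: mskpinn
Title: Physics-Informed Neural Networks for EMG-Driven Musculoskeletal
    Parameter Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single degree-of-freedom elbow flexion-extension
    dynamics driven by two antagonist Hill-type muscle-tendon actuators
    (biceps, triceps), processes raw surface electromyography into muscle
    activations, and trains physics-informed neural network surrogates that
    map sEMG signals to joint motion while simultaneously identifying
    muscle-tendon parameters (maximum isometric force and maximum
    contraction velocity) by penalizing the residual of the equation of
    motion. Provides both a time-domain surrogate with random Fourier
    features and a feature-encoded surrogate operating on Fourier plus
    quadratic-polynomial basis coefficients, a seeded synthetic-trial
    generator for verification studies, and broom-style accessors and
    ggplot2 visualizations for fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
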