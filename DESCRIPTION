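Package: wcstfocus
Title: Attentional-Focus Belief Updating Models for the Probabilistic
    Wisconsin Card Sorting Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of belief updating in a
    probabilistic Wisconsin card sorting task with belief solicitation.
    Provides the task generator (switching selection rules, noisy
    experimenter choices, money-allocation responses on the 2-simplex), a
    family of 17 behavioral models combining winner-take-all attractor or
    diffusive hidden-state dynamics with Bayesian or fixed-uncertainty
    belief updates and a logistic-normal response likelihood, Laplace
    approximation to the log model evidence via multi-restart CMA-ES, and
    random-effects Bayesian model selection with protected exceedance
    probabilities and family-wise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    mvtnorm,
    numDeriv,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
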