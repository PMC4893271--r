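Package: microdyn
Title: Dynamical Systems Inference for Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers extended generalized Lotka-Volterra (gLV) dynamical systems
    models from microbiome count time series combined with total-biomass
    measurements. Trajectories and gradients are estimated either by a
    first-order difference method or by a Bayesian negative-binomial
    penalized-spline smoother; gLV growth, interaction and perturbation
    parameters are then inferred by gradient matching using ridge regression
    (unconstrained or constrained via quadratic programming), a Bayesian
    adaptive lasso, or Bayesian variable selection with edge-inclusion
    indicators and Bayes factors. Downstream analyses include steady-state and
    Jacobian stability characterisation of sub-communities, invasion challenge
    simulation, keystoneness ranking, and a Dirichlet-multinomial simulation
    benchmark with hold-one-subject-out forecasting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
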