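Package: densitypinn
Title: Delay-Distribution Inference for Stochastic Signalling Responses
    with Density Physics-Informed Neural Networks
Version: 0.1.0
Authors@R:
    person("Density-PINN", "Maintainers", email = "maintainers@densitypinn.org",
           role = c("aut", "cre"))
Description: Estimates the signal transduction-time (delay) distribution
    g(t), the signal activation rate lambda_b, and the first-order decay
    rate lambda_d of a stochastic delayed birth-death process from response
    time traces alone.  The estimator is a physics-informed variational
    autoencoder whose decoder parameterises g(t) as a mixture of shifted
    Rayleigh kernels, trained against a data-misfit loss plus the residual
    of the population mean-field equation dy/dt = lambda_b * int_0^t g(s) ds
    - lambda_d * y(t) at collocation points.  Includes an exact delayed
    stochastic simulator with preset validation scenarios (unimodal to
    trimodal delay distributions), posterior prediction intervals, pathway
    characteristic summaries, Hartigan's dip statistic, Kullback-Leibler
    evaluation metrics, a replicated parameter-recovery harness, and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
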