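Package: gazeddm
Title: Gaze-Weighted Drift Diffusion Modelling of Value-Based Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation tools for the attentional drift
    diffusion model (aDDM) of binary value-based choice, in which the
    momentary drift rate discounts the value of the currently unfixated
    option by a gaze weight theta. Provides a millisecond-resolution
    aDDM simulator, the analytic Wiener first-passage-time likelihood
    with an outlier mixture, recovery of theta through a gaze-weighted
    drift-rate regression (subject-level maximum likelihood and a
    hierarchical Bayesian sampler with Gelman-Rubin diagnostics), the
    accompanying behavioral analyses (first-fixation and dwell-time
    regressions with cluster-robust standard errors, dwell-advantage
    choice curves, Kolmogorov-Smirnov response-time comparisons), and a
    synthetic two-condition experiment generator emulating a
    TMS-vs-control study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    sandwich,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
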