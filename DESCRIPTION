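Package: diffweight
Title: Diffusion-Based Modelling of Body Weight from Net Energy Intake
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Models weekly body-weight change as the error-function solution
    of a diffusion equation driven by net energy intake.  The weekly
    recursion f(t) = f(t-1) erf(beta) + 7 alpha l(t) [1 - erf(beta)] is fitted
    by a shuffled complex evolution Metropolis sampler (SCEM-UA) with
    Gelman-Rubin convergence checking, wrapped in an iterative
    bound-refinement loop for global optimization.  Includes resting and
    activity energy-expenditure accounting used to construct net intake, a
    synthetic-series generator for parameter-recovery studies,
    posterior-predictive prediction intervals, and the published group and
    per-subject weekly series from the Minnesota starvation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
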