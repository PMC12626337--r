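Package: ilv
Title: Iterative Lotka-Volterra Inference of Species Interactions from
    Compositional Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers generalized Lotka-Volterra (gLV) growth rates and
    pairwise interaction coefficients from relative-abundance (compositional)
    time series, where the total community size is latent. Implements the
    iterative Lotka-Volterra (iLV) estimator: an iterative gradient-matching
    subroutine that refines a pseudo-absolute-abundance linear approximation,
    followed by nonlinear least-squares refinement of the full ODE-simulated
    trajectory using several Levenberg-Marquardt-type backends. Also provides
    a gLV community simulator with configurable noise, baseline estimators
    (gradient matching on absolute or relative data, a compositional
    log-ratio surrogate, correlation screens), trajectory and cosine-similarity
    metrics, interaction-network extraction, and a benchmarking harness with
    Friedman/Wilcoxon method comparison and train/validation splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    data.table,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
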