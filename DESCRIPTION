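Package: geomort
Title: Bayesian Geostatistical Mapping of Under-Five Mortality from Cluster Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based geostatistics for under-five mortality estimated from
    DHS-style cluster surveys. Fits a Bayesian binomial spatial regression with
    survey-specific intercepts, ecological covariates and a zero-mean intrinsic
    conditional autoregressive (ICAR) Gaussian Markov random field on the raster
    lattice, by adaptive Metropolis MCMC. Includes covariate extraction and a
    collinearity screen, leave-one-out predictive checks (conditional predictive
    ordinates and probability integral transforms), WAIC model comparison,
    gridded posterior mortality surfaces, regional/national rate tables and
    trend summaries, plus a synthetic-data generator that emulates multi-survey
    cluster data with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    rlang,
    ggplot2,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
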