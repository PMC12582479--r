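Package: thermoload
Title: Bayesian State-Space Decomposition of Psychophysiological
    Responses to Repeated Temperature Steps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes repeated-measures psychophysiological time series
    recorded under alternating-room temperature-step protocols into a
    shared Base trend, condition-specific accumulated Load components with
    heavy-tailed innovations, and a damped periodic Environment component,
    using a Bayesian state-space model fitted by a blocked Gibbs sampler.
    Includes protocol/measurement-grid construction, preprocessing of raw
    R-R interval and skin-temperature streams (Burg maximum-entropy
    spectral band powers, weighted mean skin temperature, grid averaging),
    rank-normalized split R-hat and bulk effective-sample-size
    diagnostics, credible-interval comparison of conditions, section-wise
    forecasting, and a synthetic-data generator with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
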