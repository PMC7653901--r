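Package: beamdvh
Title: Beam-Informed Dose-Volume Histogram Prediction and Biologically
    Related Planning Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the composite-plan dose-volume histogram (DVH) of an
    organ at risk from the DVHs of nine equally spaced individual conformal
    beams, using a small stacked gated-recurrent-unit sequence regressor
    over a fixed percentage-volume grid. Provides the DVH quantile data
    model and resampling, dose metrics (D98, Dmax, Dmean, D1cc), equivalent
    uniform dose (EUD) with a per-organ power-law exponent registry,
    bias-corrected EUD and maximum-dose constraints for inverse planning,
    prediction-accuracy evaluation (per-organ mean error and spread,
    limits of agreement, exact paired signed-rank test), and a synthetic
    dosimetric cohort generator with known latent structure for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
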