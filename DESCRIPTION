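Package: sarsvr
Title: SAR Discontinuity Scoring and Tanimoto-Kernel Support Vector
    Regression for Compound Potency Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how epsilon-insensitive support vector
    regression (SVR) with the Tanimoto kernel handles structure-activity
    relationship (SAR) discontinuity in compound potency data. Provides
    SARI continuity/discontinuity scoring of fingerprint/potency data sets
    with reference-panel normalization, an SVR regularization sweep with a
    repeated random-split protocol, recomputation of SAR scores from
    predicted potencies in training and test context, and activity
    landscape construction (multidimensional scaling plus inverse-distance
    potency surfaces) to quantify the smoothing of predicted landscapes.
    Includes a synthetic data generator that plants analog clusters and
    activity cliffs, and a study driver that runs the whole analysis
    reproducibly from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    kernlab,
    purrr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
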