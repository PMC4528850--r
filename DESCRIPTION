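Package: knnbiomass
Title: Tree Biomass Estimation by Distance-Weighted Nearest Neighbours and
    Allometric Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Instance-based (k-nearest-neighbour) estimation of individual
    tree dry biomass from standard forest-inventory measurements, with
    leave-one-out cross-validation, four distance metrics (Euclidean,
    quadratic Euclidean, Manhattan, Chebyshev) and inverse-distance
    weighting.  Includes ordinary-least-squares fitting of the
    Schumacher-Hall log-linear allometric model with residual diagnostics
    (Shapiro-Wilk, White, Durbin-Watson), a uniform set of model-selection
    criteria (adjusted R-squared, standard error of estimate, AIC, AICc,
    BIC), a configuration-grid experiment runner for benchmarking the two
    approaches, and a seeded generator of synthetic allometric tree data
    with optional between-species heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
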