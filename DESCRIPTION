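Package: kinfed
Title: Kinetic Modeling and Control Optimization of Fed-Batch Bioprocesses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a general kinetic ordinary-differential-equation model of a
    fed-batch bioprocess (substrate uptake, growth, product formation and
    maintenance with Michaelis-Menten saturation, non-competitive inhibition
    and a thermodynamic temperature law) to multi-run time-series data.
    Observed specific rates are recovered from spline-smoothed measurements by
    the differential method; kinetic terms are pruned by a leave-one-out
    F-test backward-elimination algorithm with cross-validated choice of the
    significance level, or by exhaustive corrected-AIC search.  The fitted
    model feeds a regularized optimal-control problem (feed-rate and
    temperature profiles maximizing the final product-to-biomass yield)
    transcribed by collocation on finite elements, with a quasi-steady
    substrate variant.  Includes a response-surface-methodology baseline and
    a synthetic-data generator emulating a central composite design, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
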