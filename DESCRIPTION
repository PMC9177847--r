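Package: slfspread
Title: Stochastic Spread Modelling and ABC-SMC Calibration for the Spotted Lanternfly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A process-based, spatially explicit simulator of spotted lanternfly
    (Lycorma delicatula) invasion on a raster landscape. Reproduction is a
    Poisson process whose rate is modulated by monthly temperature coefficients
    and a seasonality mask; dispersal is a Bernoulli mixture of a half-Cauchy
    natural kernel and a railway-network kernel in which groups board a rail
    line, travel a bounded distance along the graph, and disembark anywhere
    along an edge. Parameters (beta, alpha1, gamma, d_min, d_max) are
    calibrated against presence/absence surveys with approximate Bayesian
    computation using sequential Monte Carlo, and calibrated models drive
    ensemble probability-of-occurrence forecasts with host-masked downscaling,
    zonal (county) aggregation, risk categorisation, and map comparison. A
    synthetic-scenario generator provides landscapes, rail graphs, weather and
    imperfect surveys with known ground truth so the whole pipeline is testable
    without confidential survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
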