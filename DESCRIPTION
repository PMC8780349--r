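Package: pedperm
Title: Age-Dependent Dermal Absorption Modelling and Pediatric Flux Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates percutaneous permeation through a three-layer skin model
    (stratum corneum, viable epidermis, dermis) by Fickian diffusion, with layer
    transport coefficients derived from compound physicochemical properties via
    quantitative structure-property relationships (QSPRs).  Skin-layer thicknesses
    and stratum corneum hydration mature with postnatal age according to fitted
    child:adult ratio functions; candidate maturation forms (sigmoid, Hill,
    polynomial) are fitted to literature-style ratio data by multi-start nonlinear
    least squares and selected by leave-one-out cross-validation.  An
    adult-to-child extrapolation workflow fits the uncertain stratum corneum QSPR
    parameters to adult in vitro permeation test observations and predicts
    neonatal flux with Monte Carlo uncertainty in stratum corneum thickness,
    reporting geometric-mean flux, 95% intervals and fold errors against observed
    infant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
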