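Package: tmad
Title: Trumpet Model with Axial Diffusion for Exhaled Carbon Monoxide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulmonary carbon monoxide (and nitric oxide) gas
    exchange with a one-dimensional trumpet model of the lung that includes
    gas-phase axial diffusion. Solves the advection-diffusion-source mass
    balance along the airway tree with an implicit upwind finite-volume
    scheme, drives complete breathing maneuvers (inhalation, breath-hold,
    exhalation), and records single-exhalation profiles (expirograms).
    Estimates the four governing exchange parameters (airway and alveolar
    maximum flux and diffusing capacity) from tissue, blood and anatomical
    data via a morphometric diffusing-capacity relation and the Haldane
    equation, analyzes expirograms (exhalation phases, end-tidal
    concentration, elimination rate, flow-rate sweeps, parametric
    sensitivity), and refines the exchange parameters against measured or
    synthetic expirograms by staged or joint least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
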