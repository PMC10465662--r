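Package: tdvfbc
Title: Time-Domain Vector Fitting of Lumped Outflow Boundary Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates lumped-parameter outlet boundary conditions of
    arbitrary order for blood-flow simulations from co-located pressure and
    flow-rate time series.  The order-1 case is the classical three-element
    Windkessel (RCR) model; higher orders are identified as pole-residue
    transfer functions by an extended Time-Domain Vector Fitting algorithm
    with pole relocation, a homogeneous least-squares formulation that
    estimates the distal pressure jointly with the impedance, and two
    distal-pressure estimators.  Fitted models can be exercised through a
    forward-Euler state-space runtime suitable for embedding as a boundary
    condition in 1D/3D haemodynamic solvers.  Includes a Nelder-Mead
    Windkessel baseline, a synthetic pulsatile-waveform generator with
    SNR-controlled noise, CSV/JSON readers and writers with unit conversion,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
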