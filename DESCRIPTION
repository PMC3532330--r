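Package: cmerb
Title: Parametric Model Order Reduction for the Chemical Master Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds finite state projection (FSP) approximations of the
    chemical master equation for stochastic reaction networks with
    parameter-separable propensities, trains low-dimensional reduced bases
    with the POD-Greedy algorithm, and runs fast parametric analyses
    (least-squares parameter estimation, cost landscapes, sensitivity
    sweeps) on the reduced models. Includes packaged gene-regulatory model
    fixtures: a bistable follicle switch and a stochastic genetic
    oscillator, plus an analytic birth-death oracle model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
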