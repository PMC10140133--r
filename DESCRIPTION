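Package: dvmgame
Title: Mean Field Game Models of Diel Vertical Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves a differential mean field game for diel vertical migration
    of small aquatic organisms (e.g. zooplankton) in a water column. Each agent
    controls its vertical velocity, trading off food intake near the surface
    against light-dependent visual predation risk, density-dependent mortality
    and a quadratic cost of motion, subject to random vertical displacement.
    The Nash equilibrium is characterized by a coupled time-periodic
    Fokker-Planck / Hamilton-Jacobi-Bellman system, solved here by a monolithic
    damped Newton method on a mass-conservative Scharfetter-Gummel finite
    volume discretization. An equivalent PDE-constrained optimization
    formulation (quasi-static fitness approximation) is solved independently by
    reduced-gradient ascent over the velocity field with an adjoint state.
    A reflected, killed stochastic simulator provides Monte-Carlo cross-checks
    of the density and the value function.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
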