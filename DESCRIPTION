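Package: abmode
Title: ODE Surrogate Modeling and Optimal Control of Agent-Based Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives low-dimensional ordinary-differential-equation (ODE)
    surrogate models from stochastic agent-based models (ABMs) and uses them
    to solve optimal-control problems whose solutions are lifted back to the
    ABM. Ships two reference lattice ABMs (a sheep-wolves-grass
    predator-prey model and a branched five-metabolite enzymatic pathway),
    four surrogate ODE families (mechanistic, generalized mass action,
    steady-state Taylor expansions, S-systems), trajectory averaging and
    multi-start least-squares parameterization, constant-input control
    solvers, and grid-search validation directly on the ABMs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
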