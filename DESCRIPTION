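Package: glycell
Title: Discrete Turing Patterns and Chemical Computing in Arrays of
    Coupled Glycolytic Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and bifurcation-analysis toolkit for arrays of
    mass-coupled reactor cells running the two-variable glycolytic
    (ATP/ADP activator-inhibitor) core model.  Provides the coupled-cell
    vector field with analytic Jacobian, stiff integration under
    piecewise-constant perturbation schedules, multistart Newton
    enumeration of stationary states (discrete Turing patterns) with
    symmetry classification, pseudo-arclength continuation with Hopf,
    fold and symmetry-breaking detection plus two-parameter bifurcation
    curves, and the perturbation-driven chemical logic machinery:
    central-knockout gates, truth-table synthesis, and cellular
    assemblages built from gate arrays, tautology/contradiction devices,
    clocks and two-cell memory pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
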