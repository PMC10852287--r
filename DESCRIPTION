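Package: multitroph
Title: Multi-Trophic Consumer Resource Models and Their Mean-Field Cavity Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analytic tools for random multi-trophic consumer
    resource ecosystems. Samples random three-level (plants, herbivores,
    carnivores) communities, integrates their Lotka-Volterra-type dynamics to
    steady state, and solves the matching zero-temperature cavity (mean-field)
    self-consistency equations for the truncated-Gaussian abundance laws,
    emergent competition coefficients, survival fractions, and top-down versus
    bottom-up control order parameters. Includes an N-trophic-level
    generalization, an exactly solvable single-species-per-level toy model,
    phase scans, and finite-size diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    lhs,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
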