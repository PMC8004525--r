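Package: hyperpred
Title: Apparent Competition and Hyperpredation in a Fox-Cottontail-Hare Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a three-species predator-prey model of the red fox
    (Vulpes vulpes), the invasive Eastern cottontail (Sylvilagus floridanus)
    and the native European hare (Lepus europaeus), in which the two
    lagomorphs interact only indirectly through shared fox predation.
    Provides life-history parameterization of the twelve model rates,
    closed-form equilibria with feasibility and local-stability
    classification, transcritical-bifurcation detection along one-parameter
    sweeps with Sotomayor-type transversality checks, Lyapunov-matrix
    construction for global stability, adaptive time integration with
    steady-state detection, and randomized parameter ensembles with binned
    log-hare-versus-fox regressions that exhibit the hyperpredation
    signature: the hare-fox association turns increasingly negative as
    cottontail density grows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
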