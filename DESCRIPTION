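Package: ecoepidyn
Title: Eco-Epidemiological Predator-Prey Dynamics with Behavioural
    Strategies and a Weak Allee Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical-analysis toolkit for a three-population
    eco-epidemiological model in which an infectious disease circulates in the
    prey, the predator is subject to a weak Allee effect, and the prey's
    disease-avoidance behaviour evolves by replicator (imitation) dynamics
    that modulate the transmission rate. Provides the exact model right-hand
    side with an analytic Jacobian, adaptive and fixed-step integration with
    extinction and clamping diagnostics, Newton multi-start equilibrium
    location with eigenvalue stability classification, one- and two-parameter
    bifurcation scans with attractor classification (steady state, limit
    cycle, period doubling, chaos via the largest Lyapunov exponent),
    eigenvalue-bisection stability thresholds, a registry of named scenario
    presets, tidy tibble outputs with broom-style tidiers and ggplot2
    autoplot methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
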