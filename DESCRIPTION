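Package: kairing
Title: Phase-Ring Markov-State Model of the KaiABC Circadian Oscillator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Minimal three-rung phase-ring Markov-state model of the cyanobacterial
    KaiABC post-translational oscillator. Integrates the nonlinear master equation
    dP/dt = W(P) P in which the rate matrix depends on the state through the free
    KaiA concentration, computes exact and approximate time-independent solutions,
    performs linear stability analysis of the oscillation onset (critical
    differential-affinity and ultrasensitivity parameters, predicted periods,
    Gershgorin diagnostics), evaluates entropy production rates along every edge,
    reproduces the KaiB-free ultrasensitive dose-response with effective Hill
    coefficients, and validates the mean-field description against a finite-copy
    Gillespie simulation with a shared KaiA pool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    igraph,
    optparse
Config/testthat/edition: 3
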