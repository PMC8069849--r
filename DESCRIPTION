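Package: ecoqbn
Title: Quantum-Like Bayesian Networks for Ecological Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for quantum-like Bayesian network (QBN) modelling of
    ecological systems: complex probability amplitudes and Hilbert-space state
    vectors, Born-rule measurement with collapse, interference-aware exact
    inference on amplitude-valued conditional tables, order-sensitive
    (noncommutative) evidence via amplitude-space Jeffrey conditioning,
    path-trajectory probabilities on cyclic disturbance-labelled
    state-transition graphs, and a two-oscillator phase-entrainment simulator.
    Ships executable fixtures for a bat-habitat network, the intransitive
    rock-paper-scissors game, and a boreal-forest succession cycle, together
    with JSON/CSV file dialects and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
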