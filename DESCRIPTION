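Package: prebotc
Title: Fast-Slow Analysis of a Memristive Pre-Botzinger Complex Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based model of a pre-Botzinger complex inspiratory
    neuron with persistent-sodium and calcium-activated nonspecific cation
    (CAN) currents, extended by a flux-controlled memristor that feeds an
    electromagnetic-induction current back onto the membrane. Provides stiff
    integration of the six-dimensional system and its calcium and fast
    subsystems, multi-timescale nondimensionalization, spike and interspike
    interval metrics with burst-phase segmentation, one- and two-parameter
    bifurcation analysis of the fast subsystem (folds, subcritical Hopf,
    fold of limit cycles, homoclinic and SNIC terminations), and bursting
    classification via hysteresis-loop mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
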