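Package: mlautapse
Title: Morris-Lecar Dynamics with a Delayed Excitatory Autapse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and bifurcation analysis of the two-variable
    Morris-Lecar neuron model with type II or type III excitability and an
    optional delayed excitatory autapse (a conductance-based synapse of the
    neuron onto itself). Provides a fixed-step fourth-order Runge-Kutta
    integrator with a delay history buffer, piecewise-constant stimulus
    protocols (constant currents, single pulses, periodic pulse trains),
    spike detection and interspike-interval statistics, response and
    firing-case classification, equilibrium continuation with analytic
    Jacobian eigenvalues, Hopf and fold-of-limit-cycle location, and
    parameter-plane scans over the autaptic delay, conductance and decay
    rate, including the border in the decay rate beyond which a slowly
    decaying excitatory autapse paradoxically fails to sustain firing under
    type III excitability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
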