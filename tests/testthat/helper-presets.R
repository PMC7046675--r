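# shared fixtures: the two excitability presets and the standard
# autapse-triggered run
P2 <- ml_params("typeII")
P3 <- ml_params("typeIII")
I_H_REF <- 42.797  # reference Hopf current of the type II preset

triggered_summary <- function(params, g_syn, tau, beta, t_max = 1000, ...) {
  syn <- synapse_params(g_syn = g_syn, tau = tau, beta = beta)
  tr <- ml_simulate(params, syn, trigger_protocol(), t_max = t_max)
  firing_summary(tr, I_H = I_H_REF, ...)
}
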