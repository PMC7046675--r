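#' Autapse (delayed excitatory synapse) parameters
#'
#' Parameters of the conductance-based autaptic feedback current
#' \deqn{I_{syn}(t) = -g_{syn}\, s(t - \tau)\, (V(t) - E_{syn}),}
#' where the synaptic activation s follows first-order kinetics
#' \deqn{\dot s = \alpha\, \Gamma(V - \theta_{syn})\, (1 - s) - \beta s}
#' with the steep release sigmoid
#' \eqn{\Gamma(x) = 1/(1 + e^{-k x})}. Because pre- and postsynaptic neuron
#' are the same cell, the release is driven by the neuron's own (delayed)
#' activity. With \eqn{E_{syn} = 30} mV the current is excitatory at all
#' subthreshold potentials. The decay rate \eqn{\beta} (1/ms) controls how
#' fast the activation — and hence the feedback current — decays after a
#' spike: \eqn{\beta = 1} gives a brief pulse-like current, \eqn{\beta = 0.01}
#' a slowly decaying, sustained one.
#'
#' @param g_syn autaptic conductance (mS/cm\eqn{^2}); >= 0.
#' @param tau feedback delay (ms); >= 0.
#' @param beta decay rate of the synaptic activation (1/ms); > 0.
#' @param E_syn synaptic reversal potential (mV).
#' @param alpha rise rate of the activation (1/ms); > 0.
#' @param theta_syn release threshold (mV): transmitter release occurs only
#'   when the membrane potential exceeds it, i.e. during a spike.
#' @param k_sig steepness of the release sigmoid (1/mV).
#' @return An object of class `synapse_params`.
#' @examples
#' synapse_params(g_syn = 3, tau = 15, beta = 0.1)
#' @export
synapse_params <- function(g_syn, tau, beta, E_syn = 30, alpha = 12,
                           theta_syn = 10, k_sig = 10) {
  stopifnot(g_syn >= 0, tau >= 0, alpha > 0, beta > 0)
  structure(list(g_syn = g_syn, E_syn = E_syn, tau = tau, alpha = alpha,
                 beta = beta, theta_syn = theta_syn, k_sig = k_sig),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf(
    "Autapse: g_syn = %g mS/cm^2, tau = %g ms, alpha = %g, beta = %g 1/ms\n",
    x$g_syn, x$tau, x$alpha, x$beta))
  cat(sprintf("  E_syn = %g mV, theta_syn = %g mV, k_sig = %g 1/mV\n",
              x$E_syn, x$theta_syn, x$k_sig))
  invisible(x)
}

# "no autapse": same code path with zero conductance, which leaves V and w
# arithmetic bit-identical to the synapse-free model
null_synapse <- function() synapse_params(g_syn = 0, tau = 0, beta = 1)

#' Transmitter-release sigmoid
#'
#' \eqn{\Gamma(V_{pre} - \theta_{syn}) = 1/(1 + e^{-k (V_{pre} -
#' \theta_{syn})})}: effectively 0 below the release threshold and 1 during a
#' spike, so release occurs only while the neuron spikes.
#'
#' @param V_pre presynaptic membrane potential (mV); vectorised.
#' @param synapse a [synapse_params()] object.
#' @return Value in (0, 1).
#' @export
release_sigmoid <- function(V_pre, synapse) {
  1 / (1 + exp(-synapse$k_sig * (V_pre - synapse$theta_syn)))
}

#' Synaptic activation kinetics
#'
#' Right-hand side of \eqn{\dot s = \alpha \Gamma (1-s) - \beta s}. The
#' interval \[0, 1\] is invariant: the rate is nonnegative at s = 0 and
#' nonpositive at s = 1.
#'
#' @param s activation value in \[0, 1\].
#' @param V_pre presynaptic membrane potential (mV).
#' @param synapse a [synapse_params()] object.
#' @return ds/dt in 1/ms.
#' @export
synapse_rate <- function(s, V_pre, synapse) {
  synapse$alpha * release_sigmoid(V_pre, synapse) * (1 - s) - synapse$beta * s
}

pack_params <- function(params) {
  c(params$C, params$g_Na, params$g_K, params$g_L,
    params$E_Na, params$E_K, params$E_L,
    params$beta_m, params$gamma_m, params$beta_w, params$gamma_w,
    params$phi_w, cosh_denominator(params))
}

pack_synapse <- function(synapse) {
  c(synapse$g_syn, synapse$E_syn, synapse$tau, synapse$alpha, synapse$beta,
    synapse$theta_syn, synapse$k_sig)
}

#' Integrate the model
#'
#' Advances (V, w, s) with the classical fixed-step fourth-order Runge-Kutta
#' scheme. The delayed activation \eqn{s(t - \tau)} entering the autaptic
#' current is read from the history buffer of already-computed samples, with
#' linear interpolation at the half-step stage times; the pre-run history is
#' \eqn{s(t) = 0} for \eqn{t \le 0} (no spikes before the run), so the first
#' spike must be evoked by the stimulus.
#'
#' @param params an [ml_params()] object.
#' @param synapse a [synapse_params()] object, or `NULL` for the autapse-free
#'   model.
#' @param protocol a [stimulus_protocol()]; the applied current.
#' @param t_max run length (ms).
#' @param h integration step (ms); default 0.01.
#' @param init initial state: `"equilibrium"` (default) starts from the
#'   solved resting state of the autapse-free model at the protocol baseline
#'   current, or a numeric `c(V, w)` (optionally `c(V, w, s)`).
#' @return An `ml_trajectory`: a data frame with columns `time` (ms),
#'   `V` (mV), `w`, `s` (dimensionless), `I_syn` and `I_stim`
#'   (\eqn{\mu}A/cm\eqn{^2}), with the run configuration in attributes.
#' @examples
#' p <- ml_params("typeII")
#' tr <- ml_simulate(p, protocol = standard_protocols()$long_pulse,
#'                   t_max = 200)
#' detect_spikes(tr)
#' @export
ml_simulate <- function(params, synapse = NULL, protocol, t_max = 1000,
                        h = 0.01, init = "equilibrium") {
  stopifnot(inherits(params, "ml_params"),
            inherits(protocol, "stimulus_protocol"),
            t_max > 0, h > 0)
  if (t_max < h) stop("t_max must be at least one step h")
  syn <- if (is.null(synapse)) null_synapse() else synapse
  stopifnot(inherits(syn, "synapse_params"))

  if (identical(init, "equilibrium")) {
    eq <- find_equilibrium(protocol$baseline, params)
    y0 <- c(eq$V, eq$w, 0)
  } else {
    stopifnot(is.numeric(init), length(init) %in% c(2, 3))
    y0 <- c(init, 0)[1:3]
  }

  res <- .rk4_dde_run(pack_params(params), pack_synapse(syn),
                      pack_protocol(protocol), t_max, h,
                      y0[1], y0[2], y0[3])
  n <- length(res$V)
  out <- data.frame(time = h * (seq_len(n) - 1), V = res$V, w = res$w,
                    s = res$s, I_syn = res$I_syn, I_stim = res$I_stim)
  structure(out, class = c("ml_trajectory", "data.frame"),
            params = params, synapse = if (is.null(synapse)) NULL else syn,
            protocol = protocol, h = h)
}

#' @export
print.ml_trajectory <- function(x, ...) {
  h <- attr(x, "h")
  cat(sprintf("Morris-Lecar trajectory: %d samples, %g ms at h = %g ms\n",
              nrow(x), x$time[nrow(x)], h))
  syn <- attr(x, "synapse")
  if (!is.null(syn))
    cat(sprintf("  autapse: g_syn = %g, tau = %g ms, beta = %g 1/ms\n",
                syn$g_syn, syn$tau, syn$beta))
  cat(sprintf("  V range [%.2f, %.2f] mV\n", min(x$V), max(x$V)))
  invisible(x)
}
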