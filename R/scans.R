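#' Standard trigger protocol for autapse studies
#'
#' A single brief suprathreshold pulse (1.5 ms, 100 \eqn{\mu}A/cm\eqn{^2},
#' onset 50 ms) that elicits exactly one spike; whatever happens afterwards is
#' due to the delayed autaptic feedback alone.
#'
#' @return A [stimulus_protocol()].
#' @export
trigger_protocol <- function() standard_protocols()$brief_pulse

# one triggered run + summary; shared by the scan/border/sweep routines
triggered_run <- function(params, synapse, t_max, h, settle_window,
                          steady_window, I_H = NULL) {
  tr <- ml_simulate(params, synapse, trigger_protocol(), t_max = t_max, h = h)
  firing_summary(tr, settle_window = settle_window,
                 steady_window = steady_window, I_H = I_H)
}

#' Scan the (delay, conductance) plane of the autapse
#'
#' Runs the standard triggered protocol at every grid cell of
#' (\eqn{\tau}, \eqn{g_{syn}}) for a fixed decay rate \eqn{\beta} and records
#' the firing outcome: blank (non-repetitive) cells mark the resting region,
#' and the firing region is coloured by frequency. Cells are independent and
#' deterministic, so any cell re-run standalone reproduces its grid value.
#'
#' @param beta synaptic decay rate (1/ms).
#' @param tau_range,g_range numeric `c(lo, hi)` axes (ms, mS/cm\eqn{^2}).
#' @param n_tau,n_g grid sizes.
#' @param params an [ml_params()] object.
#' @param t_max,h,settle_window,steady_window run settings per cell (ms).
#' @param I_H optional reference Hopf current for firing-case labels.
#' @return Data frame of class `ml_scan` with one row per cell: `tau`,
#'   `g_syn`, `beta`, `frequency` (spikes/s, 0 unless repetitive),
#'   `response_class`, `firing_case`, `error` (message for failed cells,
#'   otherwise `NA`).
#' @export
scan_tau_gsyn <- function(beta, tau_range = c(0.5, 30), g_range = c(0.1, 4),
                          n_tau = 60, n_g = 60, params = ml_params("typeII"),
                          t_max = 600, h = 0.01, settle_window = 200,
                          steady_window = 200, I_H = NULL) {
  taus <- seq(tau_range[1], tau_range[2], length.out = n_tau)
  gs <- seq(g_range[1], g_range[2], length.out = n_g)
  grid <- expand.grid(tau = taus, g_syn = gs)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    syn <- synapse_params(g_syn = grid$g_syn[i], tau = grid$tau[i],
                          beta = beta)
    out <- tryCatch(
      triggered_run(params, syn, t_max, h, settle_window, steady_window, I_H),
      error = function(e) e)
    if (inherits(out, "error"))
      return(data.frame(frequency = NA_real_, response_class = NA_character_,
                        firing_case = NA_character_,
                        error = conditionMessage(out)))
    freq <- if (out$response_class == "repetitive") out$frequency else 0
    data.frame(frequency = freq, response_class = out$response_class,
               firing_case = out$firing_case, error = NA_character_)
  })
  out <- cbind(grid, beta = beta, do.call(rbind, res))
  structure(out, class = c("ml_scan", "data.frame"))
}

#' @export
print.ml_scan <- function(x, ...) {
  n_rep <- sum(x$response_class == "repetitive", na.rm = TRUE)
  cat(sprintf(
    "Autapse scan (beta = %g 1/ms): %d cells, %d repetitive (%.0f%%)\n",
    x$beta[1], nrow(x), n_rep, 100 * n_rep / nrow(x)))
  invisible(x)
}

#' Firing border in the synaptic decay rate
#'
#' For type III excitability a slowly decaying excitatory autapse fails to
#' sustain firing while a faster-decaying (hence on average weaker) one
#' succeeds; this routine locates the decay-rate border between the two
#' regimes by bisection on the repetitive/non-repetitive classification of
#' the standard triggered run. A coarse geometric pre-scan first checks that
#' the classification changes exactly once across the bracket; non-monotone
#' patterns are reported instead of silently bisected.
#'
#' @param g_syn autaptic conductance (mS/cm\eqn{^2}).
#' @param tau autaptic delay (ms).
#' @param params an [ml_params()] object.
#' @param beta_lo,beta_hi decay-rate bracket (1/ms).
#' @param tol bisection bracket width (1/ms).
#' @param n_coarse points in the pre-scan.
#' @param t_max,h,settle_window run settings (ms).
#' @return List of class `beta_border`: `beta_border` (`NA` when both
#'   endpoints classify alike), `found`, `bracket`, `coarse` (the pre-scan
#'   table), `monotone`.
#' @export
firing_border_in_beta <- function(g_syn, tau, params, beta_lo = 0.01,
                                  beta_hi = 1, tol = 0.01, n_coarse = 9,
                                  t_max = 1000, h = 0.01,
                                  settle_window = 200) {
  stopifnot(beta_lo < beta_hi)
  fires <- function(beta) {
    if (g_syn == 0) return(FALSE)
    syn <- synapse_params(g_syn = g_syn, tau = tau, beta = beta)
    s <- triggered_run(params, syn, t_max, h, settle_window, settle_window)
    s$response_class == "repetitive"
  }
  betas <- exp(seq(log(beta_lo), log(beta_hi), length.out = n_coarse))
  coarse <- data.frame(beta = betas,
                       fires = vapply(betas, fires, logical(1)))
  flips <- sum(diff(coarse$fires) != 0)
  if (coarse$fires[1] == coarse$fires[n_coarse] && flips == 0)
    return(structure(list(beta_border = NA_real_, found = FALSE,
                          bracket = beta_hi - beta_lo, coarse = coarse,
                          monotone = TRUE), class = "beta_border"))
  monotone <- flips <= 1
  if (!monotone)
    warning("classification is non-monotone in beta; ",
            "bisection brackets the first change (see $coarse)")
  i <- which(diff(coarse$fires) != 0)[1]
  lo <- coarse$beta[i]; f_lo <- coarse$fires[i]
  hi <- coarse$beta[i + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid) == f_lo) lo <- mid else hi <- mid
  }
  structure(list(beta_border = (lo + hi) / 2, found = TRUE,
                 bracket = hi - lo, coarse = coarse, monotone = monotone),
            class = "beta_border")
}

#' @export
print.beta_border <- function(x, ...) {
  if (x$found)
    cat(sprintf("Firing border at beta = %.4f 1/ms (bracket %.2g)\n",
                x$beta_border, x$bracket))
  else cat("No firing border: classification identical across the range\n")
  invisible(x)
}

#' Sweep the decay rate and measure the average autaptic current
#'
#' For each decay rate \eqn{\beta}, runs the standard triggered protocol and
#' computes the time-averaged autaptic current over a fixed window, together
#' with the response classification. The default window is one interspike
#' interval of the matched fast-decay (\eqn{\beta = 1}) reference run, taken
#' from its third spike — just after the autaptic loop has engaged, an epoch
#' every run shares regardless of whether its own firing later persists —
#' and the same absolute window is used for every \eqn{\beta} so the
#' averages are comparable; the window is returned alongside the values.
#' Slower decay (smaller \eqn{\beta}) gives a larger average current — a
#' stronger mean excitatory drive — even where it fails to sustain firing.
#'
#' @param g_syn autaptic conductance (mS/cm\eqn{^2}).
#' @param tau autaptic delay (ms).
#' @param beta_values decay rates to sweep (1/ms).
#' @param params an [ml_params()] object.
#' @param window optional numeric `c(t0, t1)` (ms) overriding the reference
#'   window.
#' @param t_max,h,settle_window run settings (ms).
#' @return Data frame with `beta`, `avg_I_syn` (\eqn{\mu}A/cm\eqn{^2}),
#'   `response_class`; the measurement window is in attribute `window`.
#' @export
beta_sweep_avg_current <- function(g_syn, tau, beta_values,
                                   params = ml_params("typeII"),
                                   window = NULL, t_max = 1000, h = 0.01,
                                   settle_window = 200) {
  stopifnot(all(beta_values > 0))
  if (is.null(window)) {
    ref_syn <- synapse_params(g_syn = g_syn, tau = tau, beta = 1)
    ref <- ml_simulate(params, ref_syn, trigger_protocol(), t_max = t_max,
                       h = h)
    st <- detect_spikes(ref)
    window <- if (length(st) >= 4) st[3:4]
              else trigger_protocol()$onset + c(2, 22)  # non-firing reference
  }
  rows <- lapply(beta_values, function(b) {
    syn <- synapse_params(g_syn = g_syn, tau = tau, beta = b)
    tr <- ml_simulate(params, syn, trigger_protocol(), t_max = t_max, h = h)
    s <- firing_summary(tr, settle_window = settle_window,
                        steady_window = settle_window)
    data.frame(beta = b, avg_I_syn = average_autaptic_current(tr, window),
               response_class = s$response_class)
  })
  structure(do.call(rbind, rows), window = window)
}
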