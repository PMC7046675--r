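#' Detect spikes by threshold crossing
#'
#' A spike is counted at each upward crossing of the voltage threshold,
#' with a refractory window suppressing re-detections within the same action
#' potential. Spikes in this model overshoot 0 mV by a wide margin, so the
#' default threshold of 0 mV separates spikes cleanly from subthreshold
#' oscillations; the synaptic release threshold (10 mV) is deliberately not
#' reused here.
#'
#' @param traj an `ml_trajectory` from [ml_simulate()], or any data frame
#'   with `time` and `V` columns.
#' @param V_th detection threshold (mV).
#' @param refractory minimum separation between detected spikes (ms).
#' @return Numeric vector of spike times (ms); possibly empty.
#' @export
detect_spikes <- function(traj, V_th = 0, refractory = 1) {
  stopifnot(nrow(traj) > 0)
  V <- traj$V
  up <- which(V[-length(V)] < V_th & V[-1] >= V_th) + 1L
  times <- traj$time[up]
  if (length(times) <= 1) return(times)
  keep <- times[1]
  for (tt in times[-1]) if (tt - keep[length(keep)] >= refractory)
    keep <- c(keep, tt)
  keep
}

#' Interspike intervals
#'
#' @param spike_times spike times in ms (from [detect_spikes()]).
#' @return Successive differences (ms); empty if fewer than two spikes.
#' @export
interspike_intervals <- function(spike_times) {
  if (length(spike_times) < 2) return(numeric(0))
  diff(spike_times)
}

#' Classify the response of a run
#'
#' Distinguishes the three qualitative outcomes: `"resting"` (no spikes at
#' all), `"transient_then_rest"` (one or more spikes, but none during the
#' final settle window — a phasic, onset-only response), and `"repetitive"`
#' (spiking persists to the end of the run).
#'
#' @param spike_times spike times (ms).
#' @param traj the trajectory the spikes came from.
#' @param settle_window length of the terminal window (ms) that must contain
#'   a spike for the run to count as repetitive; the run must cover at least
#'   twice this window.
#' @return One of `"resting"`, `"transient_then_rest"`, `"repetitive"`.
#' @export
classify_response <- function(spike_times, traj, settle_window = 200) {
  t_end <- traj$time[nrow(traj)]
  if (t_end < 2 * settle_window)
    stop("run too short: need at least twice the settle window")
  if (length(spike_times) == 0) return("resting")
  if (any(spike_times > t_end - settle_window)) "repetitive"
  else "transient_then_rest"
}

#' Classify repetitive firing as case-1 or case-2
#'
#' Two mechanisms sustain autapse-driven repetitive firing. In case-1 firing
#' the delayed autaptic current arrives as brief pulses and each pulse evokes
#' the next spike, so the interspike interval tracks the delay \eqn{\tau}. In
#' case-2 firing the autaptic current stays above the Hopf current \eqn{I_H}
#' most of the time, holding the neuron beyond its rest-to-spiking transition;
#' the interval is then set by the limit-cycle period, not the delay.
#'
#' Delay entrainment is the defining feature of case-1, so it takes
#' precedence: the run is case-1 when the steady interspike interval is
#' within 15\% of \eqn{\tau}, and case-2 otherwise. The fraction of steady
#' time with \eqn{I_{syn} > I_H} corroborates a case-2 label (it exceeds 0.5
#' in sustained-drive firing) but cannot override entrainment — a slowly
#' decaying autapse can hold \eqn{I_{syn}} above \eqn{I_H} most of the time
#' even while each spike is still evoked by the delayed pulse of current.
#'
#' @param summary a [firing_summary()] (must be repetitive).
#' @param traj the underlying trajectory.
#' @param tau autaptic delay (ms); > 0.
#' @param I_H reference Hopf current (\eqn{\mu}A/cm\eqn{^2}); for the type III
#'   preset, which has no Hopf point, pass the type II value as the reference
#'   excitation level.
#' @param steady_window terminal window (ms) over which the current fraction
#'   and steady interval are measured.
#' @return `"case1"` or `"case2"`.
#' @export
classify_case <- function(summary, traj, tau, I_H, steady_window = 300) {
  if (summary$response_class != "repetitive")
    stop("firing-case classification applies only to repetitive runs")
  stopifnot(tau > 0)
  if (is.finite(summary$steady_isi) &&
      abs(summary$steady_isi - tau) / tau < 0.15) return("case1")
  "case2"
}

#' Time-averaged autaptic current
#'
#' Trapezoidal time average of \eqn{I_{syn}} over a window; used to quantify
#' the net excitatory drive the autapse delivers.
#'
#' @param traj an `ml_trajectory`.
#' @param window numeric `c(t0, t1)` (ms) inside the trajectory span.
#' @return Average current (\eqn{\mu}A/cm\eqn{^2}).
#' @export
average_autaptic_current <- function(traj, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  t_end <- traj$time[nrow(traj)]
  if (window[1] < traj$time[1] || window[2] > t_end)
    stop("window must lie inside the trajectory span")
  sel <- traj$time >= window[1] & traj$time <= window[2]
  tt <- traj$time[sel]; y <- traj$I_syn[sel]
  if (sum(sel) < 2) stop("window contains fewer than two samples")
  sum(diff(tt) * (head(y, -1) + y[-1]) / 2) / (tt[length(tt)] - tt[1])
}

#' Firing frequency over a window
#'
#' @param spike_times spike times (ms).
#' @param window numeric `c(t0, t1)` (ms) with positive length.
#' @return Spike count in the window divided by its length, in spikes/s.
#' @export
firing_frequency <- function(spike_times, window) {
  stopifnot(length(window) == 2, diff(window) > 0)
  n <- sum(spike_times >= window[1] & spike_times <= window[2])
  1000 * n / diff(window)
}

#' Summarise the firing of a run
#'
#' Detects spikes, computes interspike intervals, classifies the response,
#' and — for repetitive runs — measures the steady interspike interval and
#' firing frequency over the terminal steady window. If the run has an
#' autapse and a reference Hopf current is supplied, the firing case is also
#' labelled.
#'
#' @param traj an `ml_trajectory`.
#' @param V_th,refractory spike-detection settings (see [detect_spikes()]).
#' @param settle_window see [classify_response()].
#' @param steady_window terminal window (ms) for steady statistics.
#' @param I_H optional reference Hopf current for [classify_case()].
#' @return An object of class `firing_summary`: list with `spike_times`,
#'   `isis`, `steady_isi` (ms, `NA` unless repetitive), `frequency`
#'   (spikes/s over the steady window), `response_class`, `firing_case`.
#' @export
firing_summary <- function(traj, V_th = 0, refractory = 1,
                           settle_window = 200, steady_window = 300,
                           I_H = NULL) {
  st <- detect_spikes(traj, V_th, refractory)
  isis <- interspike_intervals(st)
  cls <- classify_response(st, traj, settle_window)
  t_end <- traj$time[nrow(traj)]
  steady_isi <- NA_real_
  if (cls == "repetitive") {
    sw <- st[st >= t_end - steady_window]
    if (length(sw) >= 2) steady_isi <- mean(diff(sw))
  }
  freq <- firing_frequency(st, c(t_end - steady_window, t_end))
  out <- structure(list(spike_times = st, isis = isis,
                        steady_isi = steady_isi, frequency = freq,
                        response_class = cls, firing_case = "not_applicable"),
                   class = "firing_summary")
  syn <- attr(traj, "synapse")
  if (cls == "repetitive" && !is.null(syn) && syn$g_syn > 0 &&
      syn$tau > 0 && !is.null(I_H)) {
    out$firing_case <- classify_case(out, traj, syn$tau, I_H, steady_window)
  }
  out
}

#' @export
print.firing_summary <- function(x, ...) {
  cat("Firing summary:", x$response_class)
  if (x$firing_case != "not_applicable") cat(" (", x$firing_case, ")", sep = "")
  cat("\n  spikes:", length(x$spike_times))
  if (is.finite(x$steady_isi))
    cat(sprintf("; steady ISI %.3f ms", x$steady_isi))
  cat(sprintf("; frequency %.1f spikes/s\n", x$frequency))
  invisible(x)
}
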