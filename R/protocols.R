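#' Piecewise-constant stimulus protocol
#'
#' Describes the applied current waveform \eqn{I_{app}(t)} for a simulation
#' run: a constant current, a single rectangular pulse, or a periodic train of
#' rectangular pulses. Pulse windows are half-open `[start, end)`, so a sample
#' exactly at a pulse end takes the baseline value.
#'
#' @param kind `"constant"`, `"pulse"`, or `"pulse_train"`.
#' @param baseline holding current (\eqn{\mu}A/cm\eqn{^2}) outside pulses.
#' @param amplitude pulse amplitude added to the baseline
#'   (\eqn{\mu}A/cm\eqn{^2}); ignored for `"constant"`.
#' @param onset time of the (first) pulse start (ms); must be >= 0.
#' @param duration pulse duration (ms); must be > 0 for pulse kinds.
#' @param period pulse-train period (ms); must exceed `duration`.
#' @param n_pulses number of pulses in a train; 0 means the train continues
#'   until the end of the run.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' # a 100 uA/cm^2, 60 ms depolarising pulse after 50 ms of rest
#' stimulus_protocol("pulse", amplitude = 100, onset = 50, duration = 60)
#' @export
stimulus_protocol <- function(kind = c("constant", "pulse", "pulse_train"),
                              baseline = 0, amplitude = 0, onset = 0,
                              duration = 0, period = NA_real_, n_pulses = 0) {
  kind <- match.arg(kind)
  stopifnot(onset >= 0, n_pulses >= 0)
  if (kind != "constant" && duration <= 0)
    stop("pulse kinds require a positive duration")
  if (kind == "pulse_train") {
    if (!is.finite(period)) stop("pulse_train requires a period")
    if (period <= duration) stop("period must exceed the pulse duration")
  }
  structure(list(kind = kind, baseline = baseline, amplitude = amplitude,
                 onset = onset, duration = duration, period = period,
                 n_pulses = as.integer(n_pulses)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol:", x$kind, "\n")
  cat(sprintf("  baseline %g uA/cm^2", x$baseline))
  if (x$kind != "constant")
    cat(sprintf("; amplitude %g, onset %g ms, duration %g ms",
                x$amplitude, x$onset, x$duration))
  if (x$kind == "pulse_train")
    cat(sprintf(", period %g ms, n_pulses %s", x$period,
                if (x$n_pulses == 0) "until end" else x$n_pulses))
  cat("\n")
  invisible(x)
}

# pack for the C++ side: kind code, baseline, amplitude, onset, duration,
# period, n_pulses
pack_protocol <- function(protocol) {
  code <- match(protocol$kind, c("constant", "pulse", "pulse_train")) - 1L
  c(code, protocol$baseline, protocol$amplitude, protocol$onset,
    protocol$duration,
    if (is.na(protocol$period)) 0 else protocol$period,
    protocol$n_pulses)
}

#' Applied current at given times
#'
#' Evaluates the piecewise-constant stimulus waveform. The function is
#' right-continuous: the pulse value holds on `[start, end)` and the baseline
#' resumes exactly at the pulse end.
#'
#' @param protocol a [stimulus_protocol()].
#' @param t time(s) in ms; must be >= 0.
#' @return Current density value(s) in \eqn{\mu}A/cm\eqn{^2}.
#' @examples
#' pr <- stimulus_protocol("pulse", amplitude = 100, onset = 50, duration = 60)
#' current_at(pr, c(49, 80, 110, 120))
#' @export
current_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (any(t < 0)) stop("stimulus times must be nonnegative")
  .stim_current_c(pack_protocol(protocol), as.numeric(t))
}

#' Standard stimulus protocols of the study conditions
#'
#' The bundle of stimulus waveforms used throughout the analyses: long
#' constant currents probing excitability class (1000 ms at 40, 50, 60, 80 and
#' 100 \eqn{\mu}A/cm\eqn{^2}), the 60 ms / 100 \eqn{\mu}A/cm\eqn{^2}
#' depolarising step, the brief 1.5 ms / 100 \eqn{\mu}A/cm\eqn{^2} trigger
#' pulse used to elicit the first spike in all autapse studies, and the
#' periodic brief-pulse train (1.5 ms pulses, 11.5 ms period). All pulses
#' start at `onset = 50` ms so the resting state is visible first.
#'
#' @return Named list of [stimulus_protocol()] objects: `constant_40`,
#'   `constant_50`, `constant_60`, `constant_80`, `constant_100`,
#'   `long_pulse`, `brief_pulse`, `pulse_train`.
#' @export
standard_protocols <- function() {
  const <- function(a) stimulus_protocol("pulse", amplitude = a, onset = 50,
                                         duration = 1000)
  list(
    constant_40 = const(40),
    constant_50 = const(50),
    constant_60 = const(60),
    constant_80 = const(80),
    constant_100 = const(100),
    long_pulse = stimulus_protocol("pulse", amplitude = 100, onset = 50,
                                   duration = 60),
    brief_pulse = stimulus_protocol("pulse", amplitude = 100, onset = 50,
                                    duration = 1.5),
    pulse_train = stimulus_protocol("pulse_train", amplitude = 100,
                                    onset = 50, duration = 1.5, period = 11.5)
  )
}
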