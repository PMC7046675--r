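make_traj <- function(time, V) {
  structure(data.frame(time = time, V = V,
                       w = 0, s = 0, I_syn = 0, I_stim = 0),
            class = c("ml_trajectory", "data.frame"), h = diff(time[1:2]))
}

test_that("spike detection counts upward crossings with a refractory window", {
  t <- seq(0, 100, 0.1)
  V <- -60 + 80 * (sin(2 * pi * t / 20) > 0.95)  # brief suprathreshold bouts
  tr <- make_traj(t, V)
  st <- detect_spikes(tr)
  expect_equal(length(st), 5)
  # refractory window suppresses double counts from wiggles inside a spike
  V2 <- V; V2[V > 0] <- V2[V > 0] + 5 * sin(50 * t[V > 0])
  expect_equal(length(detect_spikes(make_traj(t, V2))), 5)
  # invariant to adding strictly subthreshold samples
  V3 <- pmin(V, -5)
  expect_equal(length(detect_spikes(make_traj(t, V3))), 0)
})

test_that("response classification separates resting, phasic and repetitive runs", {
  # type III long pulse: exactly one spike, then rest
  tr <- ml_simulate(P3, NULL, standard_protocols()$long_pulse, t_max = 400)
  st <- detect_spikes(tr)
  expect_equal(length(st), 1)
  expect_equal(classify_response(st, tr), "transient_then_rest")
  # subthreshold constant current for type III: no spike at 60 uA/cm^2
  tr60 <- ml_simulate(P3, NULL, standard_protocols()$constant_60, t_max = 1100)
  expect_equal(classify_response(detect_spikes(tr60), tr60), "resting")
  # fast-decay autapse: repetitive
  s <- triggered_summary(P2, 3, 15, 1)
  expect_equal(s$response_class, "repetitive")
  expect_error(classify_response(1, make_traj(seq(0, 10, 1), rep(0, 11))),
               "too short")
})

test_that("single brief pulses and pulse trains evoke one spike per pulse", {
  for (p in list(P2, P3)) {
    tr <- ml_simulate(p, NULL, standard_protocols()$brief_pulse, t_max = 300)
    expect_equal(length(detect_spikes(tr)), 1)
    trn <- ml_simulate(p, NULL, standard_protocols()$pulse_train, t_max = 300)
    n_pulses <- floor((300 - 50) / 11.5) + 1
    expect_equal(length(detect_spikes(trn)), n_pulses)
  }
})

test_that("firing-case labels match the known autapse regimes", {
  # fast decay entrains both excitability types to the delay (case-1)
  expect_equal(triggered_summary(P2, 3, 15, 1)$firing_case, "case1")
  expect_equal(triggered_summary(P3, 3, 15, 1)$firing_case, "case1")
  # relatively slow decay: sustained drive for type II, entrainment for III
  expect_equal(triggered_summary(P2, 3, 15, 0.1)$firing_case, "case2")
  expect_equal(triggered_summary(P3, 3, 15, 0.1)$firing_case, "case1")
  s <- triggered_summary(P3, 3, 15, 0.1)
  expect_lt(abs(s$steady_isi - 15) / 15, 0.15)
  expect_error(classify_case(list(response_class = "resting"), NULL, 15,
                             I_H_REF), "repetitive")
})

test_that("average autaptic current is exact on known signals and linear in g_syn", {
  t <- seq(0, 10, 0.01)
  tr0 <- make_traj(t, rep(-60, length(t)))
  expect_equal(average_autaptic_current(tr0, c(1, 9)), 0)
  tr_c <- tr0; tr_c$I_syn <- rep(3.5, length(t))
  expect_equal(average_autaptic_current(tr_c, c(0, 10)), 3.5)
  # linear ramp averages to its midpoint value under the trapezoid rule
  tr_r <- tr0; tr_r$I_syn <- t
  expect_equal(average_autaptic_current(tr_r, c(2, 8)), 5)
  expect_error(average_autaptic_current(tr0, c(5, 11)), "span")
  # linearity in g_syn for identical s and V traces
  tr_g <- tr0; tr_g$I_syn <- 2 * tr_r$I_syn
  expect_equal(average_autaptic_current(tr_g, c(2, 8)),
               2 * average_autaptic_current(tr_r, c(2, 8)))
})

test_that("firing frequency is the windowed spike rate", {
  expect_equal(firing_frequency(numeric(0), c(0, 500)), 0)
  st <- seq(100, 490, 10)  # steady 10 ms ISI
  expect_equal(firing_frequency(st, c(95, 495)), 100)
  # type II at 100 uA/cm^2 fires near the reciprocal limit-cycle period
  lc <- limit_cycle_from_simulation(100, P2)
  tr <- ml_simulate(P2, NULL, stimulus_protocol("constant", baseline = 100),
                    t_max = 500, init = c(-20, 0.1))
  f <- firing_frequency(detect_spikes(tr), c(200, 500))
  expect_equal(f, 1000 / lc$period, tolerance = 0.02)
})
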