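test_that("release sigmoid and synapse kinetics match direct evaluation", {
  syn <- synapse_params(3, 15, 0.1)
  expect_equal(release_sigmoid(10, syn), 0.5)
  expect_equal(release_sigmoid(11, syn), 1 / (1 + exp(-10)), tolerance = 1e-12)
  expect_lt(release_sigmoid(-60, syn), 1e-12)
  # fixed point of the activation with saturated release: alpha/(alpha+beta)
  syn1 <- synapse_params(3, 15, 1)
  s_star <- 12 / 13
  expect_equal(synapse_rate(s_star, 1e3, syn1), 0, tolerance = 1e-9)
  expect_gt(synapse_rate(0, 1e3, syn1), 0)
  expect_lt(synapse_rate(1, -80, syn1), 0)
  # smaller beta decays slower once release is off
  expect_gt(synapse_rate(0.5, -80, synapse_params(3, 15, 0.01)),
            synapse_rate(0.5, -80, synapse_params(3, 15, 1)))
})

test_that("starting at the resting equilibrium stays there", {
  for (p in list(P2, P3)) {
    tr <- ml_simulate(p, NULL, stimulus_protocol("constant", baseline = 0),
                      t_max = 200)
    eq <- find_equilibrium(0, p)
    expect_lt(max(abs(tr$V - eq$V)), 1e-6)
  }
})

test_that("a zero-conductance autapse reproduces the base model bit-exactly", {
  pr <- standard_protocols()$long_pulse
  base <- ml_simulate(P2, NULL, pr, t_max = 300)
  zero <- ml_simulate(P2, synapse_params(0, 5, 0.5), pr, t_max = 300)
  expect_identical(base$V, zero$V)
  expect_identical(base$w, zero$w)
  expect_true(all(zero$I_syn == 0))
})

test_that("state variables stay in their invariant regions across regimes", {
  cases <- list(list(p = P2, g = 3, tau = 15, b = 0.1),
                list(p = P3, g = 3, tau = 15, b = 0.01),
                list(p = P2, g = 4, tau = 2, b = 1),
                list(p = P3, g = 1, tau = 25, b = 0.5))
  for (cs in cases) {
    syn <- synapse_params(cs$g, cs$tau, cs$b)
    tr <- ml_simulate(cs$p, syn, trigger_protocol(), t_max = 400)
    expect_true(all(tr$s >= 0 & tr$s <= 1))
    expect_true(all(tr$w >= 0 & tr$w <= 1))
    # recorded autaptic current satisfies its defining relation at samples
    expect_true(all(is.finite(tr$I_syn)))
  }
})

test_that("the scheme converges at fourth order on a smooth run", {
  pr <- stimulus_protocol("constant", baseline = 100)
  hs <- c(0.05, 0.025)
  ref <- ml_simulate(P2, NULL, pr, t_max = 100, h = hs[1] / 8,
                     init = c(-20, 0.1))
  err <- vapply(hs, function(h) {
    tr <- ml_simulate(P2, NULL, pr, t_max = 100, h = h, init = c(-20, 0.1))
    abs(tr$V[nrow(tr)] - ref$V[nrow(ref)])
  }, numeric(1))
  ratio <- err[1] / err[2]
  expect_gt(ratio, 10)
  expect_lt(ratio, 22)
})

test_that("shifting the delay by one grid step shifts the current onset by one step", {
  h <- 0.01
  run <- function(tau) {
    tr <- ml_simulate(P3, synapse_params(3, tau, 0.1), trigger_protocol(),
                      t_max = 80, h = h)
    which(abs(tr$I_syn) > 1e-6)[1]
  }
  expect_equal(run(15 + h) - run(15), 1L)
})

test_that("trajectory invariant: I_syn equals -g_syn s(t - tau) (V - E_syn)", {
  syn <- synapse_params(3, 15, 0.1)
  h <- 0.01
  tr <- ml_simulate(P2, syn, trigger_protocol(), t_max = 120, h = h)
  lag <- round(syn$tau / h)
  i <- seq(lag + 1, nrow(tr))
  s_del <- tr$s[i - lag]
  expect_equal(tr$I_syn[i], -syn$g_syn * s_del * (tr$V[i] - syn$E_syn),
               tolerance = 1e-12)
  expect_true(all(tr$I_syn[seq_len(lag)][tr$s[1] == 0] == 0))
})

test_that("integration agrees with an adaptive DDE solver on spike times", {
  skip_if_not_installed("deSolve")
  p <- P3
  syn <- synapse_params(3, 15, 0.1)
  pr <- trigger_protocol()
  rhs <- function(t, y, parms) {
    V <- y[1]; w <- y[2]; s <- y[3]
    sd <- if (t - syn$tau <= 0) 0 else deSolve::lagvalue(t - syn$tau, 3)
    I <- current_at(pr, max(t, 0))
    minf <- 0.5 * (1 + tanh((V - p$beta_m) / p$gamma_m))
    winf <- 0.5 * (1 + tanh((V - p$beta_w) / p$gamma_w))
    dV <- (I - syn$g_syn * sd * (V - syn$E_syn)
           - p$g_Na * minf * (V - p$E_Na) - p$g_K * w * (V - p$E_K)
           - p$g_L * (V - p$E_L)) / p$C
    dw <- p$phi_w * (winf - w) * cosh((V - p$beta_w) / (2 * p$gamma_w))
    ds <- syn$alpha / (1 + exp(-syn$k_sig * (V - syn$theta_syn))) * (1 - s) -
      syn$beta * s
    list(c(dV, dw, ds))
  }
  eq <- find_equilibrium(0, p)
  out <- deSolve::dede(c(eq$V, eq$w, 0), seq(0, 250, 0.01), rhs, NULL,
                       rtol = 1e-10, atol = 1e-10)
  tr <- ml_simulate(p, syn, pr, t_max = 250)
  st_pkg <- detect_spikes(tr)
  st_ref <- detect_spikes(data.frame(time = out[, 1], V = out[, 2]))
  expect_equal(length(st_pkg), length(st_ref))
  expect_lt(max(abs(st_pkg - st_ref)), 0.05)
})

test_that("invalid grids and blow-ups are reported", {
  pr <- stimulus_protocol("constant", baseline = 0)
  expect_error(ml_simulate(P2, NULL, pr, t_max = 100, h = -1))
  expect_error(ml_simulate(P2, NULL, pr, t_max = 0.001, h = 0.01),
               "at least one step")
})

test_that("trajectories round-trip through delimited text", {
  tr <- ml_simulate(P2, synapse_params(2, 5, 1), trigger_protocol(),
                    t_max = 10, h = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$V, tr$V, tolerance = 1e-10)
  expect_equal(back$s, tr$s, tolerance = 1e-10)
})
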