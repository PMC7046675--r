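test_that("equilibria reproduce the phase-plane stability picture", {
  eq0 <- find_equilibrium(0, P2)
  expect_true(eq0$stable)
  eq100 <- find_equilibrium(100, P2)
  expect_false(eq100$stable)
  # type III rest stays stable even at 100 uA/cm^2
  expect_true(find_equilibrium(100, P3)$stable)
  # focus/node comes from the discriminant: complex eigenvalues iff focus
  for (eq in list(eq0, eq100, find_equilibrium(20, P2))) {
    expect_equal(eq$type == "focus", any(Im(eq$eigenvalues) != 0))
  }
})

test_that("analytic Jacobian eigenvalues agree with central finite differences", {
  fd_jac <- function(V, w, I, p, d = 1e-6) {
    f <- function(V, w) ml_vector_field(V, w, I, p)
    cbind((f(V + d, w) - f(V - d, w)) / (2 * d),
          (f(V, w + d) - f(V, w - d)) / (2 * d))
  }
  for (p in list(P2, P3)) for (I in c(0, 42.8, 150)) {
    eq <- find_equilibrium(I, p)
    J_fd <- fd_jac(eq$V, eq$w, I, p)
    expect_equal(unname(eq$jacobian), unname(J_fd), tolerance = 1e-6)
  }
})

test_that("equilibrium branches: one stability flip for type II, none for type III", {
  br2 <- equilibrium_branch(c(0, 100), 101, P2)
  expect_equal(sum(diff(br2$stable) != 0), 1)
  expect_true(all(diff(br2$V) >= 0))
  br3 <- equilibrium_branch(c(0, 200), 101, P3)
  expect_true(all(br3$stable))
  expect_true(all(pmax(br3$re1, br3$re2) < 0))
  one <- equilibrium_branch(c(40, 40), 1, P2)
  expect_equal(one$V, find_equilibrium(40, P2)$V)
})

test_that("Hopf location is a genuine planar Hopf point", {
  hp <- find_hopf(0, 100, P2, tol = 1e-5)
  expect_true(hp$found)
  eq <- find_equilibrium(hp$I_H, P2)
  J <- eq$jacobian
  expect_lt(abs(J[1, 1] + J[2, 2]), 1e-4)        # trace crosses zero
  expect_gt(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1], 0)  # det > 0
  expect_true(all(Im(eq$eigenvalues) != 0))
  # absent outcomes: type III over the physiological range, bracket below I_H
  expect_false(find_hopf(0, 200, P3)$found)
  expect_false(find_hopf(0, 10, P2)$found)
})

test_that("limit-cycle characterisation distinguishes spiking from rest", {
  lc <- limit_cycle_from_simulation(100, P2)
  expect_true(lc$exists)
  expect_gt(lc$V_max, 0)
  expect_lt(lc$V_min, -40)
  expect_false(limit_cycle_from_simulation(100, P3)$exists)
  # below the fold, the resting equilibrium is the only attractor from rest
  expect_false(limit_cycle_from_simulation(40, P2)$exists)
})

test_that("the fold sits below the Hopf point with bistability between them", {
  hp <- find_hopf(0, 100, P2)
  fold <- find_fold_of_cycles(P2, tol = 0.02)
  expect_lt(fold$I_fold, hp$I_H)           # subcritical hysteresis window
  expect_gt(hp$I_H - fold$I_fold, 0.1)
  # inside the window the resting state is still stable...
  expect_true(find_equilibrium(42.5, P2)$stable)
  # ...and the cycle persists at 42.5 but not at 42.0 when seeded from it
  st <- unname(fold$cycle_at_fold$final_state)
  lc_hi <- limit_cycle_from_simulation(42.5, P2, init = st, t_max = 500)
  lc_lo <- limit_cycle_from_simulation(42.0, P2, init = st, t_max = 500)
  expect_true(lc_hi$exists)
  expect_false(lc_lo$exists)
  expect_error(find_fold_of_cycles(P3), "no stable cycle")
})
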