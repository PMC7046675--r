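#' Equilibrium of the autapse-free model
#'
#' Solves the intersection of the nullclines: roots of the scalar current
#' balance \eqn{F(V) = I_{app} - g_{Na} m_\infty(V)(V - E_{Na}) -
#' g_K w_\infty(V)(V - E_K) - g_L(V - E_L)} with \eqn{w^* = w_\infty(V^*)}.
#' Roots are bracketed by a sign scan over the search interval and refined
#' with [stats::uniroot()]; linear stability comes from the analytic 2x2
#' Jacobian.
#'
#' @param I_app applied current (\eqn{\mu}A/cm\eqn{^2}).
#' @param params an [ml_params()] object.
#' @param interval search interval for V (mV).
#' @param n_scan number of points in the bracketing scan.
#' @return If a single equilibrium exists, a list of class `ml_equilibrium`
#'   with `I_app`, `V`, `w`, `eigenvalues` (complex, 1/ms), `stable`, and
#'   `type` (`"focus"` or `"node"`, from the discriminant). If several roots
#'   exist, a list of such objects (caller selects).
#' @examples
#' find_equilibrium(0, ml_params("typeII"))
#' @export
find_equilibrium <- function(I_app, params, interval = c(-90, 60),
                             n_scan = 400) {
  F <- function(V) I_app - params$g_Na * m_inf(V, params) * (V - params$E_Na) -
    params$g_K * w_inf(V, params) * (V - params$E_K) -
    params$g_L * (V - params$E_L)
  Vs <- seq(interval[1], interval[2], length.out = n_scan)
  fv <- F(Vs)
  sgn <- which(fv[-1] * fv[-n_scan] <= 0 & fv[-n_scan] != 0)
  if (length(sgn) == 0) stop("no equilibrium found in the search interval")
  dF <- function(V) {
    dm <- boltzmann_slope(V, params$beta_m, params$gamma_m)
    dw <- boltzmann_slope(V, params$beta_w, params$gamma_w)
    -params$g_Na * (dm * (V - params$E_Na) + m_inf(V, params)) -
      params$g_K * (dw * (V - params$E_K) + w_inf(V, params)) - params$g_L
  }
  roots <- vapply(sgn, function(i) {
    V <- stats::uniroot(F, c(Vs[i], Vs[i + 1]), tol = 1e-10)$root
    for (k in 1:3) V <- V - F(V) / dF(V)  # Newton polish
    V
  }, numeric(1))
  roots <- sort(roots)
  roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  eqs <- lapply(roots, function(V) equilibrium_point(I_app, V, params))
  if (length(eqs) == 1) eqs[[1]] else eqs
}

equilibrium_point <- function(I_app, V, params) {
  w <- w_inf(V, params)
  J <- ml_jacobian(V, w, params)
  ev <- eigen(J, only.values = TRUE)$values
  disc <- (J[1, 1] + J[2, 2])^2 - 4 * (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
  structure(list(I_app = I_app, V = V, w = w, jacobian = J,
                 eigenvalues = ev, stable = all(Re(ev) < 0),
                 type = if (disc < 0) "focus" else "node"),
            class = "ml_equilibrium")
}

#' @export
print.ml_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium at I_app = %g: V* = %.4f mV, w* = %.5f (%s %s)\n",
              x$I_app, x$V, x$w,
              if (x$stable) "stable" else "unstable", x$type))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 5), "1/ms\n")
  invisible(x)
}

# analytic Jacobian of the planar (V, w) system
ml_jacobian <- function(V, w, params) {
  dm <- boltzmann_slope(V, params$beta_m, params$gamma_m)
  dw_inf <- boltzmann_slope(V, params$beta_w, params$gamma_w)
  d <- cosh_denominator(params)
  ch <- cosh((V - params$beta_w) / d)
  sh <- sinh((V - params$beta_w) / d)
  a11 <- (-params$g_Na * (dm * (V - params$E_Na) + m_inf(V, params)) -
            params$g_K * w - params$g_L) / params$C
  a12 <- -params$g_K * (V - params$E_K) / params$C
  a21 <- params$phi_w * (dw_inf * ch + (w_inf(V, params) - w) * sh / d)
  a22 <- -params$phi_w * ch
  matrix(c(a11, a12, a21, a22), 2, 2, byrow = TRUE)
}

#' Equilibrium branch over a current range
#'
#' Continuation of the resting state on a uniform `I_app` grid, with
#' stability flags from the analytic Jacobian.
#'
#' @param I_range numeric `c(lo, hi)` (\eqn{\mu}A/cm\eqn{^2}).
#' @param n_points number of grid points (>= 2, or 1 for a single current).
#' @param params an [ml_params()] object.
#' @return Data frame with columns `I_app`, `V`, `w`, `re1`, `re2` (real
#'   parts of the eigenvalues), `im1`, `stable`, `type`.
#' @export
equilibrium_branch <- function(I_range, n_points, params) {
  Is <- if (n_points == 1) I_range[1]
        else seq(I_range[1], I_range[2], length.out = n_points)
  rows <- lapply(Is, function(I) {
    eq <- find_equilibrium(I, params)
    if (!inherits(eq, "ml_equilibrium")) eq <- eq[[1]]
    data.frame(I_app = I, V = eq$V, w = eq$w,
               re1 = Re(eq$eigenvalues[1]), re2 = Re(eq$eigenvalues[2]),
               im1 = Im(eq$eigenvalues[1]),
               stable = eq$stable, type = eq$type)
  })
  do.call(rbind, rows)
}

#' Locate the Hopf bifurcation of the resting state
#'
#' Bisects the applied current on the sign of the larger eigenvalue real part
#' of the equilibrium. At the returned point the real part changes sign with
#' nonzero imaginary parts (a genuine Hopf, not a saddle-node): in the planar
#' system this is where the Jacobian trace crosses zero with positive
#' determinant.
#'
#' @param I_lo,I_hi bracketing currents (\eqn{\mu}A/cm\eqn{^2}).
#' @param params an [ml_params()] object.
#' @param tol bracket width at which bisection stops.
#' @return List of class `hopf_result`: `I_H` (`NA` when no stability change
#'   exists in the bracket — the expected outcome for the type III preset),
#'   `bracket` (width), `found`.
#' @examples
#' \donttest{
#' find_hopf(0, 100, ml_params("typeII"))
#' }
#' @export
find_hopf <- function(I_lo, I_hi, params, tol = 1e-4) {
  stopifnot(I_lo < I_hi)
  max_re <- function(I) {
    eq <- find_equilibrium(I, params)
    if (!inherits(eq, "ml_equilibrium")) eq <- eq[[1]]
    max(Re(eq$eigenvalues))
  }
  f_lo <- max_re(I_lo); f_hi <- max_re(I_hi)
  if (f_lo * f_hi > 0)
    return(structure(list(I_H = NA_real_, bracket = I_hi - I_lo,
                          found = FALSE), class = "hopf_result"))
  lo <- I_lo; hi <- I_hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f_lo * max_re(mid) <= 0) hi <- mid else { lo <- mid; f_lo <- max_re(lo) }
  }
  I_H <- (lo + hi) / 2
  eq <- find_equilibrium(I_H, params)
  if (!inherits(eq, "ml_equilibrium")) eq <- eq[[1]]
  if (all(Im(eq$eigenvalues) == 0))
    warning("real eigenvalues at the crossing: saddle-node, not Hopf")
  structure(list(I_H = I_H, bracket = hi - lo, found = TRUE,
                 eigenvalues = eq$eigenvalues), class = "hopf_result")
}

#' @export
print.hopf_result <- function(x, ...) {
  if (x$found)
    cat(sprintf("Hopf bifurcation at I_H = %.4f uA/cm^2 (bracket %.2g)\n",
                x$I_H, x$bracket))
  else cat("No Hopf bifurcation in the scanned current range\n")
  invisible(x)
}

#' Characterise the stable limit cycle by simulation
#'
#' Integrates the autapse-free model at a constant current and measures the
#' attractor reached: if spiking persists to the end of the run, the cycle
#' period is the mean steady interspike interval and the voltage extrema are
#' taken over the final cycles; otherwise no stable cycle is reported from
#' this initial state.
#'
#' @param I_app constant applied current (\eqn{\mu}A/cm\eqn{^2}).
#' @param params an [ml_params()] object.
#' @param init initial state passed to [ml_simulate()].
#' @param t_max run length (ms); must allow ~20 cycles at the expected period.
#' @param h integration step (ms).
#' @param settle initial transient to discard (ms).
#' @return List of class `limit_cycle`: `I_app`, `exists`, `period` (ms),
#'   `V_max`, `V_min` (mV).
#' @export
limit_cycle_from_simulation <- function(I_app, params, init = "equilibrium",
                                        t_max = 300, h = 0.01, settle = 100) {
  pr <- stimulus_protocol("constant", baseline = I_app)
  init_use <- init
  if (identical(init, "equilibrium")) {
    # perturb off the (possibly unstable) equilibrium so the attractor is found
    eq <- find_equilibrium(I_app, params)
    if (!inherits(eq, "ml_equilibrium")) eq <- eq[[1]]
    init_use <- c(eq$V + 1, eq$w)
  }
  tr <- ml_simulate(params, NULL, pr, t_max = t_max, h = h, init = init_use)
  st <- detect_spikes(tr)
  st <- st[st >= settle]
  if (length(st) < 3 || max(st) < t_max - 3 * mean(diff(st)))
    return(structure(list(I_app = I_app, exists = FALSE, period = NA_real_,
                          V_max = NA_real_, V_min = NA_real_,
                          final_state = c(V = tr$V[nrow(tr)],
                                          w = tr$w[nrow(tr)])),
                     class = "limit_cycle"))
  period <- mean(diff(st))
  last <- tr$time >= t_max - 3 * period
  structure(list(I_app = I_app, exists = TRUE, period = period,
                 V_max = max(tr$V[last]), V_min = min(tr$V[last]),
                 final_state = c(V = tr$V[nrow(tr)], w = tr$w[nrow(tr)])),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  if (x$exists)
    cat(sprintf(
      "Stable limit cycle at I_app = %g: period %.3f ms, V in [%.2f, %.2f] mV\n",
      x$I_app, x$period, x$V_min, x$V_max))
  else cat(sprintf("No stable limit cycle reached at I_app = %g\n", x$I_app))
  invisible(x)
}

#' Locate the fold (saddle-node) of limit cycles
#'
#' In the type II preset the stable spiking cycle born from the subcritical
#' Hopf point coexists with the stable resting state over a hysteresis
#' window; the cycle disappears below the Hopf current where it collides with
#' the unstable cycle. This routine follows the stable cycle downward in
#' current — each probe run is re-seeded from the final state of the previous
#' one, so the trajectory stays on the cycle branch — and then bisects the
#' smallest current at which repetitive firing persists.
#'
#' @param params an [ml_params()] object.
#' @param I_start current at which a stable cycle exists (default 100).
#' @param I_lo lower end of the search (\eqn{\mu}A/cm\eqn{^2}).
#' @param tol bisection bracket width (\eqn{\mu}A/cm\eqn{^2}).
#' @param coarse_step step of the initial downward walk.
#' @param t_probe probe run length (ms); classification discards the first
#'   `settle` ms.
#' @param h integration step (ms).
#' @param settle settle window for the repetitive classification (ms).
#' @return List of class `fold_result`: `I_fold`, `bracket`, plus the cycle
#'   at the last persisting current.
#' @export
find_fold_of_cycles <- function(params, I_start = 100, I_lo = 30, tol = 0.01,
                                coarse_step = 1, t_probe = 500, h = 0.01,
                                settle = 100) {
  persists <- function(I, state) {
    pr <- stimulus_protocol("constant", baseline = I)
    tr <- ml_simulate(params, NULL, pr, t_max = t_probe, h = h, init = state)
    st <- detect_spikes(tr)
    list(rep = classify_response(st, tr, settle_window = settle) == "repetitive",
         state = c(tr$V[nrow(tr)], tr$w[nrow(tr)]))
  }
  lc <- limit_cycle_from_simulation(I_start, params, t_max = t_probe, h = h)
  if (!lc$exists) stop("no stable cycle at I_start; fold search needs one")
  state <- unname(lc$final_state)

  # coarse descent on the cycle branch
  I <- I_start
  last_good <- I; last_state <- state
  repeat {
    I_next <- I - coarse_step
    if (I_next < I_lo) stop("cycle persisted down to I_lo; widen the search")
    res <- persists(I_next, last_state)
    if (!res$rep) break
    I <- I_next; last_good <- I; last_state <- res$state
  }

  # bisection: seed every probe from the cycle state at the last persisting I
  lo <- I - coarse_step; hi <- last_good
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    res <- persists(mid, last_state)
    if (res$rep) { hi <- mid; last_state <- res$state } else lo <- mid
  }
  structure(list(I_fold = (lo + hi) / 2, bracket = hi - lo,
                 cycle_at_fold = limit_cycle_from_simulation(
                   hi, params, init = last_state, t_max = t_probe, h = h)),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("Fold of limit cycles at I_app = %.4f uA/cm^2 (bracket %.2g)\n",
              x$I_fold, x$bracket))
  invisible(x)
}
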