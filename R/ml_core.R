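#' Morris-Lecar model parameters
#'
#' Builds the parameter set of the two-variable Morris-Lecar membrane model
#'
#' \deqn{C \dot V = I_{app} - g_{Na} m_\infty(V)(V - E_{Na})
#'       - g_K w (V - E_K) - g_L (V - E_L)}
#' \deqn{\dot w = \phi_w \, (w_\infty(V) - w) / \tau_w(V)}
#'
#' with instantaneous sodium activation \eqn{m_\infty} and a single recovery
#' variable \eqn{w} (delayed-rectifier potassium activation). Two presets are
#' provided that differ only in the half-activation voltage \eqn{\beta_w} of
#' the recovery variable: `"typeII"` (\eqn{\beta_w = -13} mV), where increasing
#' constant current destabilises the resting state through a subcritical Hopf
#' bifurcation and repetitive firing appears, and `"typeIII"`
#' (\eqn{\beta_w = -25} mV), where the resting state remains stable for all
#' constant currents in the physiological range and only phasic (onset) spikes
#' occur.
#'
#' Units are self-consistent: time in ms, potential in mV, current density in
#' \eqn{\mu}A/cm\eqn{^2}, conductance in mS/cm\eqn{^2}, capacitance in
#' \eqn{\mu}F/cm\eqn{^2}. `phi_w / tau_w(V)` acts jointly as a rate in 1/ms.
#'
#' @param preset `"typeII"` or `"typeIII"` excitability preset.
#' @param tau_w_variant form of the voltage dependence of the recovery time
#'   constant \eqn{\tau_w(V) = 1/\cosh((V-\beta_w)/d)}: `"factor_2"` uses
#'   \eqn{d = 2\gamma_w} (the standard Morris-Lecar form; default, and the
#'   form that reproduces the reference Hopf current), `"no_factor_2"` uses
#'   \eqn{d = \gamma_w}.
#' @param ... named overrides for individual fields (`C`, `g_Na`, `g_K`,
#'   `g_L`, `E_Na`, `E_K`, `E_L`, `beta_m`, `gamma_m`, `beta_w`, `gamma_w`,
#'   `phi_w`).
#'
#' @return An object of class `ml_params`: a named list of model constants.
#' @examples
#' p2 <- ml_params("typeII")
#' p3 <- ml_params("typeIII")
#' p2$beta_w - p3$beta_w  # the only difference between the presets
#' @export
ml_params <- function(preset = c("typeII", "typeIII"),
                      tau_w_variant = c("factor_2", "no_factor_2"), ...) {
  preset <- match.arg(preset)
  tau_w_variant <- match.arg(tau_w_variant)
  p <- list(
    C = 2, g_Na = 20, g_K = 20, g_L = 2,
    E_Na = 50, E_K = -100, E_L = -70,
    beta_m = -1.2, gamma_m = 18,
    beta_w = if (preset == "typeII") -13 else -25,
    gamma_w = 10, phi_w = 0.15,
    preset = preset, tau_w_variant = tau_w_variant
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), setdiff(names(p), c("preset", "tau_w_variant")))
    if (length(bad)) stop("unknown parameter override(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_ml_params(structure(p, class = "ml_params"))
}

validate_ml_params <- function(p) {
  stopifnot(p$C > 0, p$g_Na >= 0, p$g_K >= 0, p$g_L >= 0,
            p$gamma_m > 0, p$gamma_w > 0, p$phi_w > 0)
  p
}

#' @export
print.ml_params <- function(x, ...) {
  cat("Morris-Lecar parameters (", x$preset, " excitability)\n", sep = "")
  cat(sprintf("  C = %g uF/cm^2; g_Na/g_K/g_L = %g/%g/%g mS/cm^2\n",
              x$C, x$g_Na, x$g_K, x$g_L))
  cat(sprintf("  E_Na/E_K/E_L = %g/%g/%g mV\n", x$E_Na, x$E_K, x$E_L))
  cat(sprintf("  beta_m = %g, gamma_m = %g, beta_w = %g, gamma_w = %g mV; phi_w = %g\n",
              x$beta_m, x$gamma_m, x$beta_w, x$gamma_w, x$phi_w))
  cat("  tau_w variant:", x$tau_w_variant, "\n")
  invisible(x)
}

#' Boltzmann (tanh) steady-state activation
#'
#' The sigmoidal steady-state activation
#' \eqn{x_\infty(V) = 0.5 [1 + \tanh((V - \beta_x)/\gamma_x)]} used for both
#' the instantaneous sodium activation \eqn{m_\infty} and the potassium
#' steady state \eqn{w_\infty}.
#'
#' @param V membrane potential (mV); vectorised.
#' @param beta_x half-activation voltage (mV).
#' @param gamma_x slope factor (mV); must be nonzero.
#' @return Activation value in (0, 1), strictly increasing in `V` for
#'   `gamma_x > 0`.
#' @examples
#' boltzmann_activation(-1.2, beta_x = -1.2, gamma_x = 18)  # 0.5 at half-activation
#' @export
boltzmann_activation <- function(V, beta_x, gamma_x) {
  if (any(gamma_x == 0)) stop("slope factor gamma_x must be nonzero")
  0.5 * (1 + tanh((V - beta_x) / gamma_x))
}

m_inf <- function(V, params) boltzmann_activation(V, params$beta_m, params$gamma_m)
w_inf <- function(V, params) boltzmann_activation(V, params$beta_w, params$gamma_w)

# derivative of the Boltzmann activation w.r.t. V
boltzmann_slope <- function(V, beta_x, gamma_x) {
  0.5 / (cosh((V - beta_x) / gamma_x)^2 * gamma_x)
}

cosh_denominator <- function(params) {
  if (params$tau_w_variant == "factor_2") 2 * params$gamma_w else params$gamma_w
}

#' Recovery-variable time constant
#'
#' Voltage-dependent time constant of the potassium activation,
#' \eqn{\tau_w(V) = 1/\cosh((V - \beta_w)/d)} with \eqn{d = 2\gamma_w}
#' (`"factor_2"`, the standard Morris-Lecar form and package default) or
#' \eqn{d = \gamma_w} (`"no_factor_2"`). Both variants are bounded by 1,
#' symmetric about \eqn{V = \beta_w}, and maximal there.
#'
#' @param V membrane potential (mV); vectorised.
#' @param params an [ml_params()] object.
#' @param variant which cosh denominator to use; defaults to the variant
#'   recorded in `params`.
#' @return Time constant in ms, in (0, 1].
#' @export
recovery_time_constant <- function(V, params,
                                   variant = params$tau_w_variant) {
  variant <- match.arg(variant, c("factor_2", "no_factor_2"))
  d <- if (variant == "factor_2") 2 * params$gamma_w else params$gamma_w
  1 / cosh((V - params$beta_w) / d)
}

#' Morris-Lecar vector field
#'
#' Time derivatives of the membrane potential and the recovery variable at a
#' given state and applied current. The sodium activation is instantaneous
#' (\eqn{m = m_\infty(V)}); the recovery equation is
#' \eqn{\dot w = \phi_w (w_\infty(V) - w)/\tau_w(V)}.
#'
#' @param V membrane potential (mV).
#' @param w potassium activation (dimensionless, in \[0, 1\] on trajectories).
#' @param I_app applied current density (\eqn{\mu}A/cm\eqn{^2}).
#' @param params an [ml_params()] object.
#' @return Named numeric vector `c(dV = ..., dw = ...)` in mV/ms and 1/ms.
#' @examples
#' p <- ml_params("typeII")
#' eq <- find_equilibrium(0, p)
#' ml_vector_field(eq$V, eq$w, 0, p)  # ~ (0, 0) at the resting state
#' @export
ml_vector_field <- function(V, w, I_app, params) {
  if (!all(is.finite(c(V, w, I_app)))) stop("state and current must be finite")
  dV <- (I_app - params$g_Na * m_inf(V, params) * (V - params$E_Na)
         - params$g_K * w * (V - params$E_K)
         - params$g_L * (V - params$E_L)) / params$C
  dw <- params$phi_w * (w_inf(V, params) - w) /
    recovery_time_constant(V, params)
  c(dV = dV, dw = dw)
}

#' Voltage nullcline
#'
#' The curve \eqn{\dot V = 0} in the (V, w) phase plane: the potassium
#' activation w at which the membrane currents balance for a given V and
#' applied current. The nullcline moves up as `I_app` increases; its
#' intersection with the w-nullcline \eqn{w = w_\infty(V)} is the equilibrium.
#'
#' @inheritParams ml_vector_field
#' @return w value(s) on the nullcline; errors when `V == E_K` (singular
#'   potassium driving force).
#' @export
v_nullcline <- function(V, I_app, params) {
  if (any(V == params$E_K)) stop("V = E_K makes the nullcline singular")
  (I_app - params$g_Na * m_inf(V, params) * (V - params$E_Na)
    - params$g_L * (V - params$E_L)) / (params$g_K * (V - params$E_K))
}

#' Recovery nullcline
#'
#' The curve \eqn{\dot w = 0}: simply the steady-state activation
#' \eqn{w_\infty(V)}, independent of the applied current.
#'
#' @inheritParams ml_vector_field
#' @return w value(s) on the nullcline.
#' @export
w_nullcline <- function(V, params) w_inf(V, params)
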