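#' Write and read run configurations
#'
#' A run configuration (model preset plus overrides, autapse parameters,
#' stimulus protocol, integration settings) is stored as a plain-text
#' `key: value` file, one entry per line, `#` comments allowed. Synapse and
#' protocol keys are prefixed `syn_` and `stim_`.
#'
#' @param params an [ml_params()] object.
#' @param synapse a [synapse_params()] or `NULL`.
#' @param protocol a [stimulus_protocol()].
#' @param t_max,h integration settings (ms).
#' @param path file to write / read.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns a list with elements `params`, `synapse`, `protocol`, `t_max`,
#'   `h` ready to pass to [ml_simulate()].
#' @export
write_run_config <- function(params, synapse = NULL, protocol, t_max = 1000,
                             h = 0.01, path) {
  num_fields <- function(x, skip = character())
    x[setdiff(names(x), skip)]
  lines <- c("# mlautapse run configuration",
             paste0("preset: ", params$preset),
             paste0("tau_w_variant: ", params$tau_w_variant))
  for (k in names(num_fields(unclass(params), c("preset", "tau_w_variant"))))
    lines <- c(lines, sprintf("%s: %.15g", k, params[[k]]))
  if (!is.null(synapse))
    for (k in names(unclass(synapse)))
      lines <- c(lines, sprintf("syn_%s: %.15g", k, synapse[[k]]))
  lines <- c(lines, paste0("stim_kind: ", protocol$kind))
  for (k in c("baseline", "amplitude", "onset", "duration", "period",
              "n_pulses"))
    if (!is.na(protocol[[k]]))
      lines <- c(lines, sprintf("stim_%s: %.15g", k, protocol[[k]]))
  lines <- c(lines, sprintf("t_max: %.15g", t_max), sprintf("h: %.15g", h))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- readLines(path)
  raw <- trimws(sub("#.*$", "", raw))
  raw <- raw[nzchar(raw)]
  bad <- !grepl("^[A-Za-z_][A-Za-z0-9_]*\\s*:", raw)
  if (any(bad))
    stop("malformed config line ", which(bad)[1], ": '", raw[bad][1], "'")
  keys <- trimws(sub(":.*$", "", raw))
  vals <- trimws(sub("^[^:]*:", "", raw))
  kv <- stats::setNames(as.list(vals), keys)
  need <- function(k) {
    if (is.null(kv[[k]])) stop("config is missing required field '", k, "'")
    kv[[k]]
  }
  num <- function(v, k) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("config field '", k, "' is not numeric: '", v, "'")
    x
  }
  p_over <- list()
  for (k in c("C", "g_Na", "g_K", "g_L", "E_Na", "E_K", "E_L", "beta_m",
              "gamma_m", "beta_w", "gamma_w", "phi_w"))
    if (!is.null(kv[[k]])) p_over[[k]] <- num(kv[[k]], k)
  params <- do.call(ml_params,
                    c(list(preset = need("preset"),
                           tau_w_variant = if (is.null(kv$tau_w_variant))
                             "factor_2" else kv$tau_w_variant),
                      p_over))
  synapse <- NULL
  if (!is.null(kv$syn_g_syn)) {
    sk <- c("g_syn", "tau", "beta", "E_syn", "alpha", "theta_syn", "k_sig")
    sv <- list()
    for (k in sk) if (!is.null(kv[[paste0("syn_", k)]]))
      sv[[k]] <- num(kv[[paste0("syn_", k)]], paste0("syn_", k))
    synapse <- do.call(synapse_params, sv)
  }
  pk <- list(kind = need("stim_kind"))
  for (k in c("baseline", "amplitude", "onset", "duration", "period",
              "n_pulses"))
    if (!is.null(kv[[paste0("stim_", k)]]))
      pk[[k]] <- num(kv[[paste0("stim_", k)]], paste0("stim_", k))
  protocol <- do.call(stimulus_protocol, pk)
  list(params = params, synapse = synapse, protocol = protocol,
       t_max = if (is.null(kv$t_max)) 1000 else num(kv$t_max, "t_max"),
       h = if (is.null(kv$h)) 0.01 else num(kv$h, "h"))
}

#' Write and read trajectories as delimited text
#'
#' Tab-separated values with a `#` header naming the units
#' (t ms, V mV, w and s dimensionless, currents \eqn{\mu}A/cm\eqn{^2}).
#'
#' @param traj an `ml_trajectory`.
#' @param path file to write / read.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a data frame with the trajectory columns.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mlautapse trajectory",
               "# time[ms]\tV[mV]\tw[1]\ts[1]\tI_syn[uA/cm^2]\tI_stim[uA/cm^2]"),
             con)
  utils::write.table(as.data.frame(traj), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
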