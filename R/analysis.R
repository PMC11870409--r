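#' Process fluxes along a simulated trajectory
#'
#' The instantaneous molecular rate through each edge of the reaction
#' network: production \eqn{\Phi_{prod}}, secretion
#' \eqn{\Phi_{secr} = \beta I(t-\tau)}, intracellular degradation
#' \eqn{\Phi_{ideg} = \gamma I(t-\tau)}, extracellular degradation
#' \eqn{\Phi_{xdeg} = \delta X(t)}, and internalization
#' \eqn{\Phi_{int} = \epsilon X(t)} (zero when the process is absent).
#' At every time the rates balance:
#' \eqn{dI/dt = \Phi_{prod} - \Phi_{secr} - \Phi_{ideg} + \Phi_{int}} and
#' \eqn{dX/dt = \Phi_{secr} - \Phi_{xdeg} - \Phi_{int}}.
#'
#' @param traj An `"sflt_trajectory"` (delay history is taken from its
#'   attributes).
#' @param params,model Parameter set and model structure; default to those
#'   stored on the trajectory.
#' @return Data frame `time_h, phase, phi_prod, phi_secr, phi_ideg,
#'   phi_xdeg, phi_int` (#/cell/h).
#' @export
#' @examples
#' traj <- simulate_constitutive(reference_params())
#' head(fluxes(traj))
fluxes <- function(traj, params = attr(traj, "params"),
                   model = attr(traj, "model")) {
  stopifnot(inherits(traj, "sflt_trajectory"))
  p <- unclass(params)
  hist_fn <- attr(traj, "I_history")
  Id <- if (model$has_delay && p[["tau"]] > 0) {
    hist_fn(traj$time_h - p[["tau"]])
  } else {
    traj$I
  }
  chase <- traj$phase == "chase"
  phi_prod <- ifelse(chase,
                     if (model$has_production_decay) {
                       p[["alpha"]] * exp(-p[["kappa"]] * traj$time_h)
                     } else {
                       0
                     },
                     p[["alpha"]])
  data.frame(time_h = traj$time_h, phase = traj$phase,
             phi_prod = phi_prod,
             phi_secr = p[["beta"]] * Id,
             phi_ideg = p[["gamma"]] * Id,
             phi_xdeg = p[["delta"]] * traj$X,
             phi_int = p[["epsilon"]] * traj$X)
}

#' Local univariate sensitivity of constitutive-secretion outputs
#'
#' One-sided relative sensitivity: each parameter in turn is increased by
#' `bump` (default +10%), constitutive secretion is re-simulated, and the
#' sensitivity is the fractional change in the output per fractional
#' change in the parameter, \eqn{(\Delta Y/Y)/(\Delta p/p)}. Outputs are
#' extracellular and intracellular sFLT1 at the end of the simulation
#' (X72h, I72h for the default 72 h duration) and the theoretical time to
#' half-maximal extracellular sFLT1, \eqn{T_{50,X} = \ln 2/\delta}.
#'
#' @param params Baseline [sflt_params()].
#' @param model An [sflt_model()].
#' @param bump Fractional parameter increase; default 0.10.
#' @param parameters Parameters to perturb; defaults to the active core
#'   parameters (alpha, beta, gamma, delta, and tau when present).
#' @param cfg A constitutive [scenario_config()].
#' @return Data frame `parameter, output, sensitivity`.
#' @export
local_sensitivity <- function(params, model = params_model(params),
                              bump = 0.10, parameters = NULL,
                              cfg = scenario_config("constitutive")) {
  if (is.null(parameters)) {
    parameters <- intersect(c("alpha", "beta", "gamma", "delta", "tau"),
                            active_parameters(model))
  }
  outputs_of <- function(p) {
    traj <- simulate_constitutive(p, model, cfg)
    tend <- max(traj$time_h)
    c(X = trajectory_values(traj, tend, "X"),
      I = trajectory_values(traj, tend, "I"),
      T50_X = log(2) / unclass(p)[["delta"]])
  }
  base <- outputs_of(params)
  if (any(base == 0)) {
    stop("zero baseline output; sensitivity undefined", call. = FALSE)
  }
  out_names <- c(paste0("X", cfg$duration, "h"),
                 paste0("I", cfg$duration, "h"), "T50_X")
  rows <- lapply(parameters, function(nm) {
    vals <- unclass(params)
    vals[nm] <- vals[nm] * (1 + bump)
    bumped <- outputs_of(do.call(sflt_params, as.list(vals)))
    data.frame(parameter = nm, output = out_names,
               sensitivity = ((bumped - base) / base) / bump)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Global univariate sensitivity scan
#'
#' Each parameter in turn is multiplied by a grid of scaling factors
#' (default 25 log-spaced factors from 0.01 to 100) and constitutive
#' secretion is re-simulated; the end-of-simulation extracellular and
#' intracellular levels are recorded. Simulation failures at extreme
#' factors are recorded as `NA` rather than aborting the scan.
#'
#' @param params Baseline [sflt_params()].
#' @param model An [sflt_model()].
#' @param factors Multiplicative scaling factors.
#' @param parameters Parameters to scan; defaults as in
#'   [local_sensitivity()].
#' @param cfg A constitutive [scenario_config()].
#' @return Data frame `parameter, factor, value, X_end, I_end`.
#' @export
global_sensitivity <- function(params, model = params_model(params),
                               factors = 10^seq(-2, 2, length.out = 25),
                               parameters = NULL,
                               cfg = scenario_config("constitutive")) {
  if (is.null(parameters)) {
    parameters <- intersect(c("alpha", "beta", "gamma", "delta", "tau"),
                            active_parameters(model))
  }
  rows <- list()
  for (nm in parameters) {
    for (f in factors) {
      vals <- unclass(params)
      vals[nm] <- vals[nm] * f
      res <- tryCatch({
        traj <- simulate_constitutive(do.call(sflt_params,
                                              as.list(vals)),
                                      model, cfg)
        tend <- max(traj$time_h)
        c(trajectory_values(traj, tend, "X"),
          trajectory_values(traj, tend, "I"))
      }, error = function(e) c(NA_real_, NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = nm, factor = f, value = vals[[nm]],
        X_end = res[1], I_end = res[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
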