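#' Simulation protocol configuration
#'
#' Collects the settings of the two experimental scenarios. Defaults follow
#' the simulated protocols: constitutive secretion observed for 72 h (24 h
#' designs are also common), pulse-chase with a 20-minute labeling pulse
#' followed by a 10 h chase, reporting at 1-minute intervals, and a
#' pre-simulation that is considered converged once intracellular sFLT1
#' changes by less than 0.5% over a sliding 20 h window.
#'
#' @param scenario `"constitutive"` or `"pulse_chase"`.
#' @param duration Length of the reported experiment (h): the constitutive
#'   segment after media change, or the chase segment. Defaults to 72
#'   (constitutive) or 10 (pulse-chase).
#' @param pulse_length Length of the labeling pulse (h); default 1/3 h
#'   (20 min).
#' @param report_interval Reporting grid spacing (h); default 1/60 h.
#' @param ss_rel_change Relative change in I below which the
#'   pre-simulation is considered at steady state; default 0.005.
#' @param ss_window Window over which that change is measured (h);
#'   default 20.
#' @param presim_cap Maximum pre-simulation time (h); default 2000.
#' @param atol,rtol Integration tolerances; `NULL` (default) selects
#'   1e-4/1e-3 for delayed models and 1e-12/1e-8 for plain ODE models.
#'   Tighter values are useful when finite differences of the solution
#'   are taken (e.g. inside the optimizer).
#' @return A list of class `"sflt_scenario"`.
#' @export
scenario_config <- function(scenario = c("constitutive", "pulse_chase"),
                            duration = NULL, pulse_length = 1 / 3,
                            report_interval = 1 / 60,
                            ss_rel_change = 0.005, ss_window = 20,
                            presim_cap = 2000, atol = NULL, rtol = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(duration)) {
    duration <- if (scenario == "constitutive") 72 else 10
  }
  stopifnot(duration > 0, pulse_length > 0, report_interval > 0,
            report_interval <= duration, ss_rel_change > 0, ss_window > 0,
            presim_cap > ss_window)
  structure(list(scenario = scenario, duration = duration,
                 pulse_length = pulse_length,
                 report_interval = report_interval,
                 ss_rel_change = ss_rel_change, ss_window = ss_window,
                 presim_cap = presim_cap, atol = atol, rtol = rtol),
            class = "sflt_scenario")
}

# History closures are built by top-level helpers so they capture only
# the interpolation data, not the (large) calling frames.
.history_closure <- function(h_t, h_v) {
  pre_I <- stats::approxfun(h_t, h_v, rule = 2)
  function(t) pre_I(pmin(t, 0))
}

.segment_history_closure <- function(t0, t1, times, I, history_fn) {
  sol_I <- stats::approxfun(times, I, rule = 2)
  function(t) {
    ifelse(t >= t0, sol_I(pmin(t, t1)), vapply(t, history_fn, numeric(1)))
  }
}

# phase -> production mode of the compiled right-hand side
.prod_mode <- function(phase, model) {
  if (phase == "chase") {
    if (model$has_production_decay) 2 else 1
  } else {
    0
  }
}

# Sample a history function onto the uniform grid consumed by the
# compiled interpolant. Covers [t0 - tau, t0].
.set_history <- function(history_fn, t0, tau) {
  if (tau <= 0) {
    .Call("sflt_set_history", 0, 1, 0, PACKAGE = "sflt1sim")
    return(invisible())
  }
  n <- min(max(ceiling(tau * 240), 16), 4096)
  tt <- seq(t0 - tau, t0, length.out = n + 1)
  vals <- vapply(tt, history_fn, numeric(1))
  .Call("sflt_set_history", tt[1], tt[2] - tt[1], as.numeric(vals),
        PACKAGE = "sflt1sim")
  invisible()
}

#' Integrate one segment of a trafficking model
#'
#' Solves the model equations over one phase of an experimental protocol,
#' using an adaptive stiff ODE solver for models without the maturation
#' delay (absolute tolerance 1e-12, relative 1e-8) and a delay solver with
#' solution-history interpolation for delayed models (absolute tolerance
#' 1e-4, relative 1e-3). Tiny negative values arising from interpolation
#' error are clamped to 0 in the output.
#'
#' @param params An [sflt_params()] set.
#' @param model An [sflt_model()].
#' @param init Named vector or list with initial `I` and `X` (#/cell).
#' @param history Function of time returning intracellular I before the
#'   segment start (needed over `[t0 - tau, t0]` for delayed models), a
#'   single number for a constant history, or `NULL` for zero history.
#' @param t_span Numeric length-2: segment start and end times (h).
#' @param phase One of `"presim"`, `"pulse"`, `"chase"`, `"constitutive"`.
#' @param report_interval Output grid spacing (h).
#' @param chase_t0 Clock origin of the production-decay exponential (h);
#'   only used in the chase phase.
#' @param atol,rtol Integration tolerances; `NULL` selects the per-model
#'   defaults (see [scenario_config()]).
#' @return A data frame of class `"sflt_trajectory"` with columns
#'   `time_h`, `I`, `X`, `phase`, and attributes `params`, `model`, and
#'   `I_history` (an interpolant of I over the segment plus its lookback
#'   window).
#' @export
integrate_segment <- function(params, model, init, history, t_span, phase,
                              report_interval = 1 / 60, chase_t0 = 0,
                              atol = NULL, rtol = NULL) {
  check_params(params, model)
  p <- unclass(params)
  tau <- if (model$has_delay) p[["tau"]] else 0
  history_fn <- if (is.null(history)) {
    function(t) 0
  } else if (is.function(history)) {
    history
  } else {
    h0 <- as.numeric(history)
    function(t) h0
  }
  t0 <- t_span[1]
  t1 <- t_span[2]
  stopifnot(t1 > t0)
  times <- seq(t0, t1, by = report_interval)
  if (times[length(times)] < t1) times <- c(times, t1)
  y0 <- c(I = max(init[["I"]], 0), X = max(init[["X"]], 0))
  parms <- c(p[["alpha"]], p[["beta"]], p[["gamma"]], p[["delta"]], tau,
             p[["epsilon"]], p[["kappa"]], .prod_mode(phase, model),
             chase_t0, t0)
  out <- if (tau > 0) {
    .set_history(history_fn, t0, tau)
    deSolve::dede(y0, times, func = "sflt_derivs", parms = parms,
                  dllname = "sflt1sim", initfunc = "sflt_initparms",
                  atol = if (is.null(atol)) 1e-4 else atol,
                  rtol = if (is.null(rtol)) 1e-3 else rtol)
  } else {
    deSolve::ode(y0, times, func = "sflt_derivs", parms = parms,
                 dllname = "sflt1sim", initfunc = "sflt_initparms",
                 atol = if (is.null(atol)) 1e-12 else atol,
                 rtol = if (is.null(rtol)) 1e-8 else rtol)
  }
  if (attr(out, "istate")[1] < 0) {
    stop("solver failed to converge in phase '", phase, "'",
         call. = FALSE)
  }
  traj <- data.frame(time_h = out[, 1], I = pmax(out[, 2], 0),
                     X = pmax(out[, 3], 0), phase = phase,
                     stringsAsFactors = FALSE)
  lookback <- max(tau, report_interval)
  I_history <- .segment_history_closure(t0, t1, traj$time_h, traj$I,
                                        history_fn)
  structure(traj,
            class = c("sflt_trajectory", "data.frame"),
            params = params, model = model, I_history = I_history,
            lookback = lookback)
}

#' Run the pre-simulation to intracellular steady state
#'
#' Starting from an empty system (I = X = 0, zero history), integrates
#' constitutive production until the intracellular level changes by less
#' than `ss_rel_change` over a sliding window of `ss_window` hours,
#' evaluated on the reporting grid with first-crossing semantics. An empty
#' system with no production (both window endpoints zero) counts as
#' converged.
#'
#' @param params An [sflt_params()] set.
#' @param model An [sflt_model()].
#' @param cfg A [scenario_config()] (the steady-state fields are used).
#' @return A list with `state` (named vector `I`, `X` at convergence),
#'   `history` (function of t <= 0 giving I on the media-change clock,
#'   i.e. shifted so that convergence is at time 0), and `t_converged`
#'   (pre-simulation hours elapsed).
#' @export
run_to_steady_state <- function(params, model,
                                cfg = scenario_config("constitutive")) {
  check_params(params, model)
  dt <- cfg$report_interval
  wpts <- round(cfg$ss_window / dt)
  chunk <- max(10 * cfg$ss_window, 100)
  t_grid <- numeric(0)
  I_acc <- numeric(0)
  X_acc <- numeric(0)
  t_done <- 0
  state <- c(I = 0, X = 0)
  history <- NULL # zero history initially
  repeat {
    t_end <- min(t_done + chunk, cfg$presim_cap)
    seg <- integrate_segment(params, model, state, history,
                             c(t_done, t_end), "presim",
                             report_interval = dt,
                             atol = cfg$atol, rtol = cfg$rtol)
    keep <- if (length(t_grid)) -1L else TRUE # drop duplicated joint point
    t_grid <- c(t_grid, seg$time_h[keep])
    I_acc <- c(I_acc, seg$I[keep])
    X_acc <- c(X_acc, seg$X[keep])
    idx <- seq_along(I_acc)
    cand <- idx[idx > wpts]
    if (length(cand)) {
      prev <- I_acc[cand - wpts]
      cur <- I_acc[cand]
      # zero/zero guard (production-free systems): the whole window must
      # be extinct, not just its endpoints -- strongly delayed parameter
      # regions oscillate through 0 and must not count as converged
      csum <- cumsum(I_acc)
      win_sum <- csum[cand] - csum[cand - wpts]
      ok <- ifelse(prev > 0, abs(cur - prev) / prev < cfg$ss_rel_change,
                   win_sum == 0)
      hit <- cand[which(ok)[1]]
      if (length(hit) && !is.na(hit)) {
        t_star <- t_grid[hit]
        # keep only the delay lookback window of the pre-simulation,
        # shifted onto the media-change clock (t = 0 at convergence)
        tau <- if (model$has_delay) unclass(params)[["tau"]] else 0
        sel <- t_grid >= t_star - (tau + 1) & t_grid <= t_star
        return(list(
          state = c(I = I_acc[hit], X = X_acc[hit]),
          history = .history_closure(t_grid[sel] - t_star, I_acc[sel]),
          t_converged = t_star))
      }
    }
    t_done <- t_end
    state <- c(I = seg$I[nrow(seg)], X = seg$X[nrow(seg)])
    history <- attr(seg, "I_history")
    if (t_done >= cfg$presim_cap) {
      stop("pre-simulation did not reach steady state within ",
           cfg$presim_cap, " h", call. = FALSE)
    }
  }
}

#' Simulate a constitutive secretion experiment
#'
#' Runs the pre-simulation to intracellular steady state, then applies a
#' media change at t = 0: extracellular sFLT1 is reset to 0 while the
#' intracellular level and its delay history are carried over unchanged.
#' The experiment is then integrated for `cfg$duration` hours with
#' reporting on the configured grid.
#'
#' @inheritParams run_to_steady_state
#' @param cfg A [scenario_config()] with `scenario = "constitutive"`.
#' @return An `"sflt_trajectory"` data frame covering `[0, duration]`, all
#'   rows in phase `"constitutive"`, with attribute `presim` holding the
#'   [run_to_steady_state()] result.
#' @export
#' @examples
#' traj <- simulate_constitutive(reference_params(), sflt_model("M2"))
#' traj[traj$time_h %in% c(0, 24, 72), ]
simulate_constitutive <- function(params, model = params_model(params),
                                  cfg = scenario_config("constitutive")) {
  stopifnot(cfg$scenario == "constitutive")
  ss <- run_to_steady_state(params, model, cfg)
  traj <- integrate_segment(params, model,
                            init = c(I = ss$state[["I"]], X = 0),
                            history = ss$history, t_span = c(0, cfg$duration),
                            phase = "constitutive",
                            report_interval = cfg$report_interval,
                            atol = cfg$atol, rtol = cfg$rtol)
  attr(traj, "presim") <- ss
  attr(traj, "scenario") <- cfg
  traj
}

#' Simulate a pulse-chase experiment
#'
#' Only newly synthesized (labeled) protein is tracked, so the system
#' starts empty with zero history: production runs for `cfg$pulse_length`
#' hours (the labeling pulse, times reported on a negative clock ending at
#' 0), then at t = 0 the media change resets X to 0 without changing I and
#' production switches off (or decays as \eqn{\alpha e^{-\kappa t}} for
#' models with production decay). The chase is integrated for
#' `cfg$duration` hours.
#'
#' @inheritParams run_to_steady_state
#' @param cfg A [scenario_config()] with `scenario = "pulse_chase"`.
#' @param include_pulse Keep the pulse-phase rows (negative times) in the
#'   returned trajectory; default TRUE.
#' @return An `"sflt_trajectory"` data frame with phases `"pulse"` and
#'   `"chase"`.
#' @export
simulate_pulse_chase <- function(params, model = params_model(params),
                                 cfg = scenario_config("pulse_chase"),
                                 include_pulse = TRUE) {
  stopifnot(cfg$scenario == "pulse_chase")
  pulse <- integrate_segment(params, model, init = c(I = 0, X = 0),
                             history = NULL,
                             t_span = c(-cfg$pulse_length, 0),
                             phase = "pulse",
                             report_interval = cfg$report_interval,
                             atol = cfg$atol, rtol = cfg$rtol)
  chase <- integrate_segment(params, model,
                             init = c(I = pulse$I[nrow(pulse)], X = 0),
                             history = attr(pulse, "I_history"),
                             t_span = c(0, cfg$duration), phase = "chase",
                             report_interval = cfg$report_interval,
                             chase_t0 = 0,
                             atol = cfg$atol, rtol = cfg$rtol)
  traj <- if (include_pulse) {
    rbind(pulse[-nrow(pulse), ], chase)
  } else {
    chase
  }
  pulse_hist <- attr(pulse, "I_history")
  chase_hist <- attr(chase, "I_history")
  structure(traj,
            class = c("sflt_trajectory", "data.frame"),
            params = params, model = model,
            I_history = function(t) {
              ifelse(t >= 0, chase_hist(t), pulse_hist(t))
            },
            scenario = cfg)
}

#' Normalize a trajectory to anchor time points
#'
#' Converts a #/cell trajectory to relative units by dividing X by its
#' value at `anchor_X` and I by its value at `anchor_I`, the way Western
#' blot time courses are normalized to one lane.
#'
#' @param traj An `"sflt_trajectory"`.
#' @param anchor_X,anchor_I Anchor times (h); must have positive values in
#'   the trajectory. Pass `NULL` to leave a species unscaled.
#' @return The trajectory in relative units (attribute `units` set to
#'   `"relative"`, with the anchors recorded).
#' @export
normalize_trajectory <- function(traj, anchor_X = NULL, anchor_I = NULL) {
  stopifnot(inherits(traj, "sflt_trajectory"))
  at <- function(col, t) {
    v <- stats::approx(traj$time_h, traj[[col]], xout = t)$y
    if (is.na(v)) stop("anchor time ", t, " outside trajectory",
                       call. = FALSE)
    v
  }
  out <- traj
  if (!is.null(anchor_X)) {
    aX <- at("X", anchor_X)
    if (aX <= 0) stop("zero anchor value for X at ", anchor_X, " h",
                      call. = FALSE)
    out$X <- out$X / aX
  }
  if (!is.null(anchor_I)) {
    aI <- at("I", anchor_I)
    if (aI <= 0) stop("zero anchor value for I at ", anchor_I, " h",
                      call. = FALSE)
    out$I <- out$I / aI
  }
  attr(out, "units") <- "relative"
  attr(out, "anchors") <- list(X = anchor_X, I = anchor_I)
  out
}

#' Export a trajectory to tidy CSV
#'
#' One row per (time, species), columns `time_h, species, value, phase,
#' units`.
#'
#' @param traj An `"sflt_trajectory"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  units <- attr(traj, "units")
  if (is.null(units)) units <- "#/cell"
  tidy <- rbind(
    data.frame(time_h = traj$time_h, species = "I", value = traj$I,
               phase = traj$phase, units = units),
    data.frame(time_h = traj$time_h, species = "X", value = traj$X,
               phase = traj$phase, units = units))
  utils::write.csv(tidy, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate trajectory values at arbitrary times
#'
#' Linear interpolation on the reporting grid.
#'
#' @param traj An `"sflt_trajectory"`.
#' @param times Times (h) inside the trajectory span.
#' @param species `"I"` or `"X"`.
#' @return Numeric vector of interpolated values.
#' @export
trajectory_values <- function(traj, times, species = c("X", "I")) {
  species <- match.arg(species)
  if (any(times < min(traj$time_h) - 1e-9) ||
      any(times > max(traj$time_h) + 1e-9)) {
    stop("requested times outside the simulated span", call. = FALSE)
  }
  stats::approx(traj$time_h, traj[[species]], xout = times, rule = 2)$y
}
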