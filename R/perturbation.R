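#' Fractional inhibition of one trafficking process
#'
#' A perturbation multiplies one process parameter by `(1 - fraction)`.
#' `"chemical"` mode represents acute drug addition: the pre-simulation
#' runs with baseline parameters and the reduced parameter takes effect at
#' the media change (t = 0). `"genetic"` mode represents chronic
#' downregulation (e.g. siRNA applied days earlier): the reduced parameter
#' applies throughout, including the pre-simulation.
#'
#' @param target One of `"alpha"`, `"beta"`, `"gamma"`, `"delta"`,
#'   `"tau"`.
#' @param fraction Fractional inhibition f in `[0, 1]`.
#' @param mode `"chemical"` or `"genetic"`.
#' @return A list of class `"sflt_inhibition"`.
#' @export
inhibition_spec <- function(target = c("alpha", "beta", "gamma", "delta",
                                       "tau"),
                            fraction, mode = c("chemical", "genetic")) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) {
    stop("fraction inhibition must be in [0, 1]", call. = FALSE)
  }
  structure(list(target = target, fraction = fraction, mode = mode),
            class = "sflt_inhibition")
}

.apply_inhibition <- function(params, inh) {
  vals <- unclass(params)
  vals[inh$target] <- (1 - inh$fraction) * vals[inh$target]
  do.call(sflt_params, as.list(vals))
}

#' Simulate constitutive secretion under inhibition
#'
#' Identical to [simulate_constitutive()] except that one process
#' parameter is reduced to `(1 - f) * p`: at the media change only
#' (chemical mode) or throughout including the pre-simulation (genetic
#' mode).
#'
#' @param params Baseline [sflt_params()].
#' @param inh An [inhibition_spec()].
#' @param model An [sflt_model()].
#' @param cfg A constitutive [scenario_config()].
#' @return An `"sflt_trajectory"` over `[0, duration]`.
#' @export
#' @examples
#' inh <- inhibition_spec("alpha", 0.9, "genetic")
#' traj <- simulate_inhibited(reference_params(), inh)
simulate_inhibited <- function(params, inh,
                               model = params_model(params),
                               cfg = scenario_config("constitutive")) {
  stopifnot(inherits(inh, "sflt_inhibition"))
  inhibited <- .apply_inhibition(params, inh)
  if (inh$mode == "genetic") {
    return(simulate_constitutive(inhibited, model, cfg))
  }
  ss <- run_to_steady_state(params, model, cfg) # baseline pre-simulation
  traj <- integrate_segment(inhibited, model,
                            init = c(I = ss$state[["I"]], X = 0),
                            history = ss$history,
                            t_span = c(0, cfg$duration),
                            phase = "constitutive",
                            report_interval = cfg$report_interval,
                            atol = cfg$atol, rtol = cfg$rtol)
  attr(traj, "presim") <- ss
  attr(traj, "scenario") <- cfg
  attr(traj, "inhibition") <- inh
  traj
}

#' Fold changes of an inhibited trajectory relative to control
#'
#' @param inhibited,control `"sflt_trajectory"` objects on compatible
#'   grids.
#' @param times Times (h) at which to report, e.g. `c(18, 72)`.
#' @param species Species to report; default both.
#' @return Data frame `species, time_h, fold_change, log2_fold_change`.
#' @export
fold_changes <- function(inhibited, control, times = c(18, 72),
                         species = c("I", "X")) {
  rows <- lapply(species, function(sp) {
    ctrl <- trajectory_values(control, times, sp)
    if (any(ctrl <= 0)) {
      stop("control value is zero at a requested time; fold change ",
           "undefined", call. = FALSE)
    }
    fc <- trajectory_values(inhibited, times, sp) / ctrl
    data.frame(species = sp, time_h = times, fold_change = fc,
               log2_fold_change = log2(fc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Invert an observed fold change into a fraction inhibition
#'
#' Finds the fraction inhibition f of the target parameter for which the
#' simulated fold change (inhibited / control) of the observed species at
#' the observed time equals the experimental value. The simulated
#' response is first evaluated on a grid of f values to verify
#' monotonicity and feasibility; the root is then bisected to the
#' requested tolerance. Infeasible observations yield a verdict instead
#' of an estimate: `"infeasible: exceeds full inhibition"` when even f = 1
#' cannot reach the observed magnitude, `"infeasible: wrong direction"`
#' when the observed change has the opposite sign to the simulated
#' response.
#'
#' @param observed Observed fold change (> 0) relative to control.
#' @param species `"I"` or `"X"`.
#' @param time Observation time (h), e.g. 18.
#' @param target Parameter targeted by the inhibitor.
#' @param mode `"chemical"` or `"genetic"`.
#' @param params Baseline [sflt_params()].
#' @param model An [sflt_model()].
#' @param cfg A constitutive [scenario_config()] (its duration must cover
#'   `time`).
#' @param n_scan Number of f grid points in the monotonicity pre-scan.
#' @param tol Absolute tolerance on f.
#' @return A list of class `"sflt_inversion"`: `feasible`, `f` (estimate
#'   or NA), `verdict`, `observed`, `response_range`, and the scanned
#'   `scan` data frame.
#' @export
invert_inhibition <- function(observed, species, time, target, mode,
                              params, model = params_model(params),
                              cfg = scenario_config("constitutive"),
                              n_scan = 21, tol = 1e-3) {
  stopifnot(observed > 0, time <= cfg$duration)
  control <- simulate_constitutive(params, model, cfg)
  g <- function(f) {
    inh <- inhibition_spec(target, f, mode)
    traj <- simulate_inhibited(params, inh, model, cfg)
    fold_changes(traj, control, times = time,
                 species = species)$fold_change
  }
  fs <- seq(0, 1, length.out = n_scan)
  gs <- vapply(fs, g, numeric(1))
  scan <- data.frame(f = fs, fold_change = gs)
  d <- diff(gs)
  # differences below the integration noise floor count as flat
  flat_tol <- 1e-5 * max(abs(gs))
  if (all(abs(d) <= flat_tol)) {
    return(structure(list(feasible = FALSE, f = NA_real_,
                          verdict = "response insensitive to target",
                          observed = observed,
                          response_range = range(gs), scan = scan),
                     class = "sflt_inversion"))
  }
  signs <- sign(d[abs(d) > flat_tol])
  if (length(unique(signs)) > 1) {
    stop("simulated fold change is not monotone in the inhibition ",
         "fraction; refusing to bisect", call. = FALSE)
  }
  increasing <- signs[1] > 0
  lo <- min(gs)
  hi <- max(gs)
  if (observed < lo || observed > hi) {
    wrong_dir <- if (increasing) observed < gs[1] else observed > gs[1]
    verdict <- if (wrong_dir) {
      "infeasible: wrong direction"
    } else {
      "infeasible: exceeds full inhibition"
    }
    return(structure(list(feasible = FALSE, f = NA_real_,
                          verdict = verdict, observed = observed,
                          response_range = c(lo, hi), scan = scan),
                     class = "sflt_inversion"))
  }
  # bracket on the pre-scan grid, then bisect f itself to tolerance
  idx <- which((gs[-length(gs)] - observed) * (gs[-1] - observed) <= 0)[1]
  f_lo <- fs[idx]
  f_hi <- fs[idx + 1]
  root <- stats::uniroot(function(f) g(f) - observed,
                         lower = f_lo, upper = f_hi, tol = tol / 4)
  structure(list(feasible = TRUE, f = root$root, verdict = "feasible",
                 observed = observed, response_range = c(lo, hi),
                 scan = scan),
            class = "sflt_inversion")
}

#' @export
print.sflt_inversion <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("fraction inhibition f = %.3f (observed fold change %g)\n",
                x$f, x$observed))
  } else {
    cat(x$verdict, sprintf(
      "(observed %g, attainable range [%.3g, %.3g])\n", x$observed,
      x$response_range[1], x$response_range[2]))
  }
  invisible(x)
}

#' Fold-change surfaces across the constrained family of parameter sets
#'
#' Spans the one remaining degree of freedom of the fitted model by
#' constructing baseline parameter sets with the secretion rate constant
#' at chosen fractions of c2 (via [params_from_beta()]), then simulates
#' chemical or genetic inhibition of each target over a grid of
#' inhibition fractions, recording intracellular and extracellular fold
#' changes at the requested times.
#'
#' @param c1,c2,delta,tau Constraint constants shared by all baselines.
#' @param beta_fractions Fractions of c2 at which to place beta; default
#'   `c(0.2, 0.4, 0.6, 0.8, 1)`.
#' @param targets Parameters to inhibit; default
#'   `c("alpha","beta","gamma","delta")`.
#' @param fractions Inhibition fractions f; default `seq(0, 0.95, 0.05)`.
#' @param times Report times (h); default `c(18, 72)`.
#' @param modes `"chemical"`, `"genetic"` or both.
#' @param cfg A constitutive [scenario_config()].
#' @return Tidy data frame `beta_fraction, beta, target, mode, f,
#'   species, time_h, fold_change, log2_fold_change`.
#' @export
inhibition_scan <- function(c1, c2, delta, tau,
                            beta_fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                            targets = c("alpha", "beta", "gamma",
                                        "delta"),
                            fractions = seq(0, 0.95, by = 0.05),
                            times = c(18, 72),
                            modes = c("chemical", "genetic"),
                            cfg = scenario_config("constitutive")) {
  rows <- list()
  for (bf in beta_fractions) {
    base <- params_from_beta(bf * c2, c1, c2, delta, tau)
    model <- params_model(base)
    control <- simulate_constitutive(base, model, cfg)
    for (target in targets) {
      for (mode in modes) {
        for (f in fractions) {
          traj <- simulate_inhibited(base,
                                     inhibition_spec(target, f, mode),
                                     model, cfg)
          fc <- fold_changes(traj, control, times = times)
          fc$beta_fraction <- bf
          fc$beta <- bf * c2
          fc$target <- target
          fc$mode <- mode
          fc$f <- f
          rows[[length(rows) + 1]] <- fc
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("beta_fraction", "beta", "target", "mode", "f", "species",
          "time_h", "fold_change", "log2_fold_change")]
}
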