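#' Multistart fit configuration
#'
#' Controls the multistart bounded least-squares optimization. Initial
#' guesses are sampled log-uniformly within `sampling_ranges` for the rate
#' parameters, whose plausible values span orders of magnitude, and
#' uniformly for the maturation delay, whose range includes 0. The search
#' is bounded by `bounds` (defaulting to the sampling ranges, except that
#' the optional-process parameters tau, epsilon and kappa may reach 0 so
#' that every candidate model contains its sub-models on the boundary).
#'
#' @param n_starts Number of optimization starts.
#' @param sampling_ranges Named list of `c(low, high)` per parameter.
#' @param bounds Named list of `c(low, high)` per parameter.
#' @param seed Master seed for initial-guess sampling.
#' @param filter_rel Fits with cost within this fraction of the minimum
#'   are "accepted"; default 0.10.
#' @param cost_floor Costs below this value are treated as numerically
#'   equivalent to zero when applying the acceptance filter (relative
#'   comparisons are meaningless at the solver noise floor); default 1e-4.
#' @param ftol,ptol Least-squares convergence tolerances (relative
#'   reduction in the sum of squares / in the parameters).
#' @param maxiter Maximum optimizer iterations per start.
#' @param penalty Residual value substituted when a trial simulation
#'   fails, so the optimizer retreats from pathological regions.
#' @param sim_atol,sim_rtol Integration tolerances used for simulations
#'   inside the optimizer. Tighter than the reporting defaults so that
#'   finite-difference derivatives of the cost are not dominated by
#'   solver noise.
#' @param epsfcn Relative step factor for the optimizer's
#'   finite-difference jacobian (the step is about `sqrt(epsfcn)` times
#'   the parameter); chosen to stay above the integration noise floor.
#' @return A list of class `"sflt_fit_config"`.
#' @export
fit_config <- function(n_starts = 100,
                       sampling_ranges = list(
                         alpha = c(1e3, 1e7), beta = c(1e-4, 10),
                         gamma = c(1e-4, 10), delta = c(1e-4, 10),
                         tau = c(0, 8), epsilon = c(1e-4, 10),
                         kappa = c(1e-2, 1e4)),
                       bounds = NULL, seed = 1L, filter_rel = 0.10,
                       cost_floor = 1e-4, ftol = 1e-8, ptol = 1e-8,
                       maxiter = 100, penalty = 1e3,
                       sim_atol = 1e-2, sim_rtol = 1e-6,
                       epsfcn = 1e-6) {
  if (is.null(bounds)) {
    bounds <- sampling_ranges
    for (nm in intersect(c("tau", "epsilon", "kappa"), names(bounds))) {
      bounds[[nm]][1] <- 0
    }
  }
  for (nm in names(sampling_ranges)) {
    r <- sampling_ranges[[nm]]
    if (r[1] > r[2]) stop("invalid sampling range for ", nm,
                          call. = FALSE)
  }
  stopifnot(n_starts >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 sampling_ranges = sampling_ranges, bounds = bounds,
                 seed = as.integer(seed), filter_rel = filter_rel,
                 cost_floor = cost_floor, ftol = ftol, ptol = ptol,
                 maxiter = maxiter, penalty = penalty,
                 sim_atol = sim_atol, sim_rtol = sim_rtol,
                 epsfcn = epsfcn),
            class = "sflt_fit_config")
}

# Note on nesting: a model without the delay or internalization process
# sits on the tau = 0 / epsilon = 0 boundary of the larger model, but a
# model without production decay is the kappa -> Inf limit of the decay
# models (decayed production during the chase vanishes instantly), so
# kappa's bounds extend high enough for that limit to be approached.

# parameters optimized on a log10 scale (strictly positive rates);
# the optional-process parameters stay linear so 0 is reachable
.LOG_PARAMS <- c("alpha", "beta", "gamma", "delta")

.to_opt <- function(values, names) {
  ifelse(names %in% .LOG_PARAMS, log10(values), values)
}

.from_opt <- function(values, names) {
  ifelse(names %in% .LOG_PARAMS, 10^values, values)
}

#' Sample initial parameter guesses
#'
#' Reproducible log-uniform (rates) / uniform (delay) samples within the
#' configured ranges, for the parameters active in the model.
#'
#' @param cfg A [fit_config()].
#' @param model An [sflt_model()].
#' @return List of [sflt_params()] starts of length `cfg$n_starts`.
#' @export
sample_initial_guesses <- function(cfg, model = sflt_model("M2")) {
  stopifnot(inherits(cfg, "sflt_fit_config"))
  act <- active_parameters(model)
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_starts), function(i) {
    vals <- stats::setNames(numeric(length(.PARAM_NAMES)), .PARAM_NAMES)
    for (nm in act) {
      r <- cfg$sampling_ranges[[nm]]
      vals[nm] <- if (r[1] > 0) {
        10^stats::runif(1, log10(r[1]), log10(r[2]))
      } else {
        stats::runif(1, r[1], r[2])
      }
    }
    do.call(sflt_params, as.list(vals))
  })
}

# Simulate the scenarios needed by a set of datasets for one parameter
# vector, sharing simulations across datasets and caching the
# pre-simulation steady state by the parameters it depends on.
.simulate_scenarios <- function(params, model, needs, cache = NULL,
                                atol = NULL, rtol = NULL) {
  sims <- list()
  for (key in names(needs)) {
    spec <- needs[[key]]
    if (spec$scenario == "constitutive") {
      cfg <- scenario_config("constitutive", duration = spec$duration,
                             atol = atol, rtol = rtol)
      ss <- NULL
      if (!is.null(cache)) {
        p <- unclass(params)
        dep <- c(p[["alpha"]], p[["beta"]], p[["gamma"]], p[["tau"]],
                 if (model$has_internalization) c(p[["delta"]],
                                                 p[["epsilon"]]))
        ck <- paste(format(dep, digits = 17), collapse = "|")
        ss <- cache[[ck]]
        if (is.null(ss)) {
          ss <- run_to_steady_state(params, model, cfg)
          # the cache only needs to span one jacobian sweep
          if (length(ls(cache)) > 20) rm(list = ls(cache), envir = cache)
          cache[[ck]] <- ss
        }
      } else {
        ss <- run_to_steady_state(params, model, cfg)
      }
      traj <- integrate_segment(params, model,
                                init = c(I = ss$state[["I"]], X = 0),
                                history = ss$history,
                                t_span = c(0, cfg$duration),
                                phase = "constitutive",
                                report_interval = cfg$report_interval,
                                atol = cfg$atol, rtol = cfg$rtol)
      sims[[key]] <- traj
    } else {
      cfg <- scenario_config("pulse_chase", duration = spec$duration,
                             atol = atol, rtol = rtol)
      sims[[key]] <- simulate_pulse_chase(params, model, cfg)
    }
  }
  sims
}

.scenario_needs <- function(datasets) {
  needs <- list()
  for (ds in datasets) {
    tmax <- max(ds$observations$time_h)
    if (ds$units == "relative") {
      tmax <- max(tmax, ds$anchor_time_X, ds$anchor_time_I)
    }
    dur <- if (ds$scenario == "constitutive") {
      max(72, ceiling(tmax))
    } else {
      max(10, ceiling(tmax))
    }
    key <- paste(ds$scenario, dur, sep = "_")
    needs[[key]] <- list(scenario = ds$scenario, duration = dur)
  }
  needs
}

#' Relative-error residuals of a model against datasets
#'
#' Simulates each dataset's scenario under `params`, converts predictions
#' into the dataset's units, and returns one unweighted relative error
#' `(simulated - experimental) / experimental` per observation.
#'
#' @param params An [sflt_params()] set.
#' @param model An [sflt_model()].
#' @param datasets List of `"sflt_dataset"` objects (preprocessed
#'   automatically).
#' @param atol,rtol Integration tolerances; `NULL` uses the reporting
#'   defaults.
#' @return Numeric residual vector with attribute `dataset` labelling each
#'   entry.
#' @export
fit_residuals <- function(params, model, datasets, atol = NULL,
                          rtol = NULL) {
  if (inherits(datasets, "sflt_dataset")) datasets <- list(datasets)
  datasets <- lapply(datasets, function(d) {
    if (d$preprocessed) d else preprocess_dataset(d)
  })
  for (ds in datasets) {
    if (any(ds$observations$value == 0)) {
      stop("dataset '", ds$name, "' contains zero observations; ",
           "relative error undefined", call. = FALSE)
    }
  }
  needs <- .scenario_needs(datasets)
  sims <- .simulate_scenarios(params, model, needs, atol = atol,
                              rtol = rtol)
  res <- numeric(0)
  labels <- character(0)
  for (ds in datasets) {
    key <- names(.scenario_needs(list(ds)))
    pred <- predict_in_dataset_units(sims[[key]], ds)
    r <- (pred$predicted - ds$observations$value) /
      ds$observations$value
    res <- c(res, r)
    labels <- c(labels, rep(ds$name, length(r)))
  }
  attr(res, "dataset") <- labels
  res
}

# Build the optimizer objective: transformed active-parameter vector ->
# residual vector, with failures mapped to a finite penalty.
.make_objective <- function(model, datasets, cfg) {
  act <- active_parameters(model)
  needs <- .scenario_needs(datasets)
  keys <- vapply(datasets, function(d) names(.scenario_needs(list(d))),
                 character(1))
  n_obs <- sum(vapply(datasets, function(d) nrow(d$observations),
                      integer(1)))
  obs_values <- lapply(datasets, function(d) d$observations$value)
  cache <- new.env(parent = emptyenv())
  function(par_t) {
    vals <- stats::setNames(numeric(length(.PARAM_NAMES)), .PARAM_NAMES)
    vals[act] <- .from_opt(par_t, act)
    params <- do.call(sflt_params, as.list(vals))
    res <- tryCatch({
      sims <- .simulate_scenarios(params, model, needs, cache,
                                  atol = cfg$sim_atol,
                                  rtol = cfg$sim_rtol)
      unlist(lapply(seq_along(datasets), function(i) {
        pred <- predict_in_dataset_units(sims[[keys[i]]], datasets[[i]])
        (pred$predicted - obs_values[[i]]) / obs_values[[i]]
      }))
    }, error = function(e) rep(cfg$penalty, n_obs))
    res[!is.finite(res)] <- cfg$penalty
    res
  }
}

#' Multistart bounded least-squares fit of one candidate model
#'
#' Runs bounded Levenberg-Marquardt least squares on the relative-error
#' residual vector from each sampled start (plus any `extra_starts`), and
#' filters the converged fits to the accepted subset: cost within
#' `filter_rel` of the minimum (with costs below `cost_floor` treated as
#' ties at the numerical-zero floor).
#'
#' @param model An [sflt_model()].
#' @param datasets List of `"sflt_dataset"` objects.
#' @param cfg A [fit_config()].
#' @param extra_starts Optional list of [sflt_params()] appended to the
#'   sampled starts (e.g. warm starts from nested models).
#' @return A list of class `"sflt_fit_ensemble"`: `results` (one row per
#'   start: start and fitted parameter values, cost, per-dataset costs,
#'   convergence and acceptance flags), `model`, `config`, `n_obs`,
#'   `datasets` (names).
#' @export
fit_multistart <- function(model, datasets, cfg = fit_config(),
                           extra_starts = NULL) {
  if (inherits(datasets, "sflt_dataset")) datasets <- list(datasets)
  datasets <- lapply(datasets, function(d) {
    if (d$preprocessed) d else preprocess_dataset(d)
  })
  for (ds in datasets) {
    if (any(ds$observations$value == 0)) {
      stop("dataset '", ds$name, "' contains zero observations; ",
           "relative error undefined", call. = FALSE)
    }
  }
  act <- active_parameters(model)
  starts <- sample_initial_guesses(cfg, model)
  if (!is.null(extra_starts)) starts <- c(starts, extra_starts)
  objective <- .make_objective(model, datasets, cfg)
  lower <- .to_opt(vapply(cfg$bounds[act], `[`, numeric(1), 1), act)
  upper <- .to_opt(vapply(cfg$bounds[act], `[`, numeric(1), 2), act)
  ds_labels <- vapply(datasets, function(d) d$name, character(1))
  ds_sizes <- vapply(datasets, function(d) nrow(d$observations),
                     integer(1))
  ds_index <- rep(seq_along(datasets), ds_sizes)
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    st <- unclass(starts[[i]])
    par0 <- pmin(pmax(.to_opt(st[act], act), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = objective,
                         control = minpack.lm::nls.lm.control(
                           ftol = cfg$ftol, ptol = cfg$ptol,
                           maxiter = cfg$maxiter,
                           epsfcn = cfg$epsfcn)),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[i]] <- NULL
      next
    }
    fitted <- stats::setNames(numeric(length(.PARAM_NAMES)),
                              .PARAM_NAMES)
    fitted[act] <- .from_opt(fit$par, act)
    res <- objective(fit$par)
    cost <- sum(res^2)
    per_ds <- vapply(seq_along(datasets),
                     function(k) sum(res[ds_index == k]^2), numeric(1))
    row <- c(list(start = i), as.list(st[act]), cost = cost,
             converged = fit$info %in% 1:4, info = fit$info,
             niter = fit$niter)
    names(row)[2:(1 + length(act))] <- paste0("start_", act)
    row <- c(row, as.list(stats::setNames(fitted[act], act)),
             as.list(stats::setNames(per_ds, paste0("cost_", ds_labels))))
    rows[[i]] <- as.data.frame(row)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("all optimization starts failed", call. = FALSE)
  results <- do.call(rbind, rows)
  conv <- results[results$converged, , drop = FALSE]
  if (nrow(conv)) {
    min_cost <- min(conv$cost)
    threshold <- max((1 + cfg$filter_rel) * min_cost, cfg$cost_floor)
    results$accepted <- results$converged & results$cost <= threshold
  } else {
    results$accepted <- FALSE
  }
  structure(list(results = results, model = model, config = cfg,
                 n_obs = sum(ds_sizes), datasets = ds_labels),
            class = "sflt_fit_ensemble")
}

#' @export
print.sflt_fit_ensemble <- function(x, ...) {
  cat("sFLT1 multistart fit, model ", x$model$model_id, ": ",
      nrow(x$results), " starts, ", sum(x$results$converged),
      " converged, ", sum(x$results$accepted), " accepted\n",
      "  min cost ", format(min(x$results$cost), digits = 4), " over ",
      x$n_obs, " observations (", paste(x$datasets, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Extract the accepted (or best) parameter sets from an ensemble
#'
#' @param ensemble An `"sflt_fit_ensemble"`.
#' @param which `"accepted"` for all accepted fits, `"best"` for the
#'   single lowest-cost converged fit.
#' @return List of [sflt_params()] (length 1 for `"best"`).
#' @export
ensemble_params <- function(ensemble, which = c("accepted", "best")) {
  which <- match.arg(which)
  res <- ensemble$results
  sel <- if (which == "accepted") {
    res[res$accepted, , drop = FALSE]
  } else {
    res[res$converged, , drop = FALSE][which.min(res$cost[res$converged]),
                                       , drop = FALSE]
  }
  act <- active_parameters(ensemble$model)
  lapply(seq_len(nrow(sel)), function(i) {
    vals <- stats::setNames(numeric(length(.PARAM_NAMES)), .PARAM_NAMES)
    vals[act] <- unlist(sel[i, act])
    do.call(sflt_params, as.list(vals))
  })
}

#' Summary statistics of an accepted fit ensemble
#'
#' Per-parameter and compound-constant (c1, c2) statistics over the
#' accepted fits: mean, SD, CV, median, MAD (median absolute deviation,
#' unscaled), IQR, min, max. Also reports the theoretical intracellular
#' steady state of each fit.
#'
#' @param ensemble An `"sflt_fit_ensemble"` with a non-empty accepted set.
#' @return Data frame with one row per quantity.
#' @export
summarize_ensemble <- function(ensemble) {
  res <- ensemble$results
  acc <- res[res$accepted, , drop = FALSE]
  if (!nrow(acc)) stop("no accepted fits to summarize", call. = FALSE)
  act <- active_parameters(ensemble$model)
  quantities <- c(act, "c1", "c2", "I_SS")
  vals <- cbind(acc[, act, drop = FALSE],
                c1 = acc$alpha * acc$beta,
                c2 = acc$beta + acc$gamma,
                I_SS = acc$alpha / (acc$beta + acc$gamma))
  stat_row <- function(v) {
    m <- mean(v)
    data.frame(mean = m, sd = stats::sd(v),
               cv = if (m != 0) stats::sd(v) / m else 0,
               median = stats::median(v),
               mad = stats::mad(v, constant = 1),
               iqr = stats::IQR(v), min = min(v), max = max(v))
  }
  out <- do.call(rbind, lapply(quantities, function(q) {
    cbind(data.frame(parameter = q), stat_row(vals[[q]]))
  }))
  if (nrow(acc) == 1) out$sd <- out$cv <- out$mad <- out$iqr <- 0
  rownames(out) <- NULL
  out
}

#' Export a fit ensemble to CSV (one row per start) plus a JSON summary
#'
#' @param ensemble An `"sflt_fit_ensemble"`.
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON summary path.
#' @return `csv_path`, invisibly.
#' @export
export_ensemble <- function(ensemble, csv_path, json_path = NULL) {
  utils::write.csv(ensemble$results, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- summarize_ensemble(ensemble)
    jsonlite::write_json(
      list(model = ensemble$model$model_id, n_obs = ensemble$n_obs,
           n_starts = nrow(ensemble$results),
           n_accepted = sum(ensemble$results$accepted),
           min_cost = min(ensemble$results$cost), summary = summ),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(csv_path)
}
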