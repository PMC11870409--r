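#' Design of a synthetic sFLT1 secretion dataset
#'
#' Templates emulate the structure of three published experimental
#' designs for sFLT1 secretion by cultured endothelial cells:
#' \describe{
#'   \item{`hornig_like`}{constitutive secretion, extracellular sFLT1
#'     only, absolute concentration units (ELISA-like, ng/mL), sampled at
#'     1, 3, 6, 12, 24, 48, 72 h with the 3 h point pre-flagged excluded
#'     (below a typical ELISA limit of quantitation).}
#'   \item{`kinghorn_like`}{constitutive secretion, extracellular and
#'     intracellular sFLT1, relative units (quantitative-Western-like),
#'     out to 72 h; X normalized at 24 h, I at 0 h. X is not measured at
#'     0 h, where the media change sets it to zero by construction.}
#'   \item{`jung_like`}{20-minute pulse then 10 h chase, both species,
#'     relative units on the chase clock; X normalized at 8 h, I at 0 h,
#'     with the 10 h X point pre-flagged excluded.}
#' }
#' All defaults are overridable. Measurement noise is multiplicative
#' lognormal per observation with the given coefficient of variation.
#'
#' @param template One of `"hornig_like"`, `"kinghorn_like"`,
#'   `"jung_like"`.
#' @param noise_cv Coefficient of variation of the lognormal noise;
#'   default 0.10. Use 0 for noiseless data.
#' @param replicates Replicates per time point; default 3.
#' @param seed Seed for noise generation.
#' @param name Dataset label; defaults to the template name.
#' @param times_X,times_I Measurement time grids per species (h); `NULL`
#'   omits the species.
#' @param excluded Data frame `time_h, species` of points to pre-flag as
#'   excluded.
#' @param units,anchor_time_X,anchor_time_I,conversion Overrides of the
#'   template's measurement units and metadata (see [new_dataset()]).
#' @param species Restrict the measured species, e.g. `"I"` for an
#'   intracellular-only variant of a template.
#' @return A list of class `"sflt_design"`.
#' @export
synthetic_design <- function(template = c("hornig_like", "kinghorn_like",
                                          "jung_like"),
                             noise_cv = 0.10, replicates = 3, seed = 1L,
                             name = NULL, times_X = NULL, times_I = NULL,
                             excluded = NULL, units = NULL,
                             anchor_time_X = NULL, anchor_time_I = NULL,
                             conversion = NULL, species = NULL) {
  template <- match.arg(template)
  stopifnot(noise_cv >= 0, replicates >= 1)
  defaults <- switch(template,
    hornig_like = list(
      scenario = "constitutive",
      times_X = c(1, 3, 6, 12, 24, 48, 72), times_I = NULL,
      excluded = data.frame(time_h = 3, species = "X"),
      units = "absolute_concentration",
      anchor_time_X = NULL, anchor_time_I = NULL,
      conversion = list(cells_per_volume = 1e5, molar_mass = 1.1e5)),
    kinghorn_like = list(
      scenario = "constitutive",
      times_X = c(2, 4, 8, 24, 48, 72),
      times_I = c(0, 2, 4, 8, 24, 48, 72),
      excluded = NULL, units = "relative",
      anchor_time_X = 24, anchor_time_I = 0, conversion = NULL),
    jung_like = list(
      scenario = "pulse_chase",
      times_X = c(2, 3, 4, 6, 8, 10),
      times_I = c(0, 0.5, 1, 2, 4, 6, 8, 10),
      excluded = data.frame(time_h = 10, species = "X"),
      units = "relative",
      anchor_time_X = 8, anchor_time_I = 0, conversion = NULL))
  pick <- function(given, def) if (is.null(given)) def else given
  times_X <- pick(times_X, defaults$times_X)
  times_I <- pick(times_I, defaults$times_I)
  if (!is.null(species)) {
    stopifnot(all(species %in% c("I", "X")))
    if (!"X" %in% species) times_X <- NULL
    if (!"I" %in% species) times_I <- NULL
  }
  structure(list(template = template, scenario = defaults$scenario,
                 times_X = times_X,
                 times_I = times_I,
                 excluded = pick(excluded, defaults$excluded),
                 units = pick(units, defaults$units),
                 anchor_time_X = pick(anchor_time_X,
                                      defaults$anchor_time_X),
                 anchor_time_I = pick(anchor_time_I,
                                      defaults$anchor_time_I),
                 conversion = pick(conversion, defaults$conversion),
                 noise_cv = noise_cv,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 name = pick(name, template)),
            class = "sflt_design")
}

#' Generate a synthetic dataset from a model
#'
#' Simulates the design's scenario under the generating parameters,
#' evaluates the noiseless trajectory at the design's time grid (in the
#' design's units: normalized at the anchors for relative designs,
#' converted to ng/mL for absolute designs), and applies independent
#' multiplicative lognormal noise with the design's CV to each replicate
#' observation. Deterministic under the design's seed.
#'
#' @param params Generating [sflt_params()].
#' @param design A [synthetic_design()].
#' @param model An [sflt_model()].
#' @return An `"sflt_dataset"` carrying the design as attribute
#'   `"design"`.
#' @export
#' @examples
#' d <- synthetic_design("kinghorn_like", noise_cv = 0)
#' ds <- generate_dataset(reference_params(), d)
generate_dataset <- function(params, design,
                             model = params_model(params)) {
  stopifnot(inherits(design, "sflt_design"))
  cfg <- if (design$scenario == "constitutive") {
    tmax <- max(72, design$times_X, design$times_I,
                design$anchor_time_X, design$anchor_time_I)
    scenario_config("constitutive", duration = tmax)
  } else {
    tmax <- max(10, design$times_X, design$times_I,
                design$anchor_time_X, design$anchor_time_I)
    scenario_config("pulse_chase", duration = tmax)
  }
  traj <- if (design$scenario == "constitutive") {
    simulate_constitutive(params, model, cfg)
  } else {
    simulate_pulse_chase(params, model, cfg)
  }
  grids <- list(X = design$times_X, I = design$times_I)
  truth <- do.call(rbind, lapply(c("X", "I"), function(sp) {
    tt <- grids[[sp]]
    if (is.null(tt)) return(NULL)
    v <- trajectory_values(traj, tt, sp)
    if (design$units == "relative") {
      a <- if (sp == "X") design$anchor_time_X else design$anchor_time_I
      a_val <- trajectory_values(traj, a, sp)
      if (a_val <= 0) {
        stop("anchor time with zero noiseless value for ", sp,
             call. = FALSE)
      }
      v <- v / a_val
    } else {
      conv <- design$conversion
      v <- v * conv$cells_per_volume * conv$molar_mass / .AVOGADRO * 1e9
    }
    data.frame(time_h = tt, species = sp, value = v,
               stringsAsFactors = FALSE)
  }))
  set.seed(design$seed)
  obs <- do.call(rbind, lapply(seq_len(design$replicates), function(r) {
    noisy <- truth
    if (design$noise_cv > 0) {
      sdlog <- sqrt(log(1 + design$noise_cv^2))
      noisy$value <- noisy$value *
        stats::rlnorm(nrow(noisy), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    noisy$replicate <- r
    noisy
  }))
  obs$excluded <- FALSE
  if (!is.null(design$excluded)) {
    for (i in seq_len(nrow(design$excluded))) {
      sel <- obs$time_h == design$excluded$time_h[i] &
        obs$species == design$excluded$species[i]
      obs$excluded[sel] <- TRUE
    }
  }
  ds <- new_dataset(name = design$name, scenario = design$scenario,
                    observations = obs, units = design$units,
                    anchor_time_X = design$anchor_time_X,
                    anchor_time_I = design$anchor_time_I,
                    conversion = design$conversion)
  attr(ds, "design") <- design
  attr(ds, "generating_params") <- params
  ds
}

#' Parameter-recovery experiment on synthetic data
#'
#' Generates datasets from known parameters, fits the model by multistart
#' least squares, and compares the accepted-ensemble medians (parameters
#' and compound constants) against the generating values.
#'
#' @param params Generating [sflt_params()].
#' @param designs List of [synthetic_design()]s.
#' @param fit_cfg A [fit_config()].
#' @param model An [sflt_model()].
#' @return A list of class `"sflt_recovery"`: `ensemble`, `summary`
#'   (ensemble statistics), `errors` (per-quantity generating value,
#'   recovered median, relative error, and ensemble CV), and `datasets`.
#' @export
recovery_experiment <- function(params, designs, fit_cfg = fit_config(),
                                model = params_model(params)) {
  if (inherits(designs, "sflt_design")) designs <- list(designs)
  datasets <- lapply(designs, function(d) generate_dataset(params, d,
                                                           model))
  ens <- fit_multistart(model, datasets, fit_cfg)
  summ <- summarize_ensemble(ens)
  cc <- compound_constants(params)
  gen <- c(unclass(params)[active_parameters(model)],
           c1 = cc$c1, c2 = cc$c2,
           I_SS = steady_state(params)$I_SS)
  errors <- do.call(rbind, lapply(names(gen), function(q) {
    row <- summ[summ$parameter == q, ]
    data.frame(parameter = q, generating = gen[[q]],
               recovered_median = row$median,
               rel_error = abs(row$median - gen[[q]]) /
                 ifelse(gen[[q]] != 0, abs(gen[[q]]), 1),
               ensemble_cv = row$cv,
               spread = ifelse(row$min > 0, row$max / row$min, Inf))
  }))
  rownames(errors) <- NULL
  structure(list(ensemble = ens, summary = summ, errors = errors,
                 datasets = datasets, generating = params),
            class = "sflt_recovery")
}

#' @export
print.sflt_recovery <- function(x, ...) {
  cat("Parameter recovery from synthetic data (model ",
      x$ensemble$model$model_id, ", ", sum(x$ensemble$results$accepted),
      " accepted fits)\n", sep = "")
  print(x$errors, row.names = FALSE, digits = 3)
  invisible(x)
}
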