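# deterministic per-stage seed derived from the master seed (double
# arithmetic: products exceed integer range but stay exact below 2^53)
.stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 2654435 + h * 97) %% 2147483647)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a file path or a list", call. = FALSE)
  }
}

.write_manifest <- function(out_dir, command, config, seed, artifacts) {
  manifest <- list(command = command, config = config, seed = seed,
                   artifacts = artifacts,
                   package_version = as.character(
                     utils::packageVersion("sflt1sim")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.cfg_params <- function(config) {
  if (!is.null(config$params_file)) {
    read_params(config$params_file)
  } else if (!is.null(config$params)) {
    do.call(sflt_params, config$params)
  } else {
    reference_params()
  }
}

.cfg_datasets <- function(config) {
  if (is.null(config$datasets)) stop("config lacks 'datasets' paths",
                                     call. = FALSE)
  missing <- config$datasets[!file.exists(unlist(config$datasets))]
  if (length(missing)) {
    stop("dataset file(s) not found: ",
         paste(unlist(missing), collapse = ", "), call. = FALSE)
  }
  lapply(config$datasets, load_dataset)
}

.cfg_fit <- function(config, seed) {
  args <- config$fit
  if (is.null(args)) args <- list()
  if (is.null(args$seed)) args$seed <- .stage_seed(seed, "fit")
  do.call(fit_config, args)
}

#' Run one stage of the sFLT1 modeling pipeline
#'
#' Configuration-driven entry point tying the package's stages together.
#' Each command reads its inputs from `config` (an R list or the path of
#' a YAML/JSON file), writes tidy CSV/JSON artifacts plus a
#' `manifest.json` (config echo, seed, versions) into `out_dir`, and
#' returns the artifact paths invisibly. One master seed governs all
#' stochastic stages; stage seeds are derived deterministically from it,
#' so identical config + seed reproduce identical artifacts.
#'
#' Commands and their main config keys:
#' \describe{
#'   \item{`simulate`}{`model`, `params_file`/`params`, `scenario`,
#'     `duration` -> `trajectory.csv`}
#'   \item{`synth`}{`template`, `noise_cv`, `replicates`,
#'     `params_file` -> `dataset.csv` + `dataset.yaml`}
#'   \item{`fit`}{`datasets` (CSV paths), `model`, `fit` (fit_config
#'     arguments) -> `ensemble.csv`, `fit_summary.json`}
#'   \item{`compare-models`}{`datasets`, `fit` -> `model_comparison.csv`}
#'   \item{`sensitivity`}{`params_file` -> `local_sensitivity.csv`,
#'     `global_sensitivity.csv`}
#'   \item{`fluxes`}{`params_file`, `scenario` -> `fluxes.csv`}
#'   \item{`inhibit`}{`target`, `fraction`, `mode` -> `inhibited.csv`,
#'     `fold_changes.csv`}
#'   \item{`invert`}{`observations` (CSV with columns species, time_h,
#'     fold_change, target, mode) -> `inversion.json`}
#'   \item{`recover`}{`templates`, `noise_cv`, `fit` -> `recovery.json`}
#' }
#'
#' @param command One of the subcommands above.
#' @param config R list or path to a YAML/JSON config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, a character vector of artifact paths.
#' @export
run_pipeline <- function(command, config = list(), out_dir = ".",
                         seed = 1L) {
  config <- .load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)
  params <- NULL
  model <- NULL
  if (!command %in% c("fit", "compare-models")) {
    params <- .cfg_params(config)
    model <- if (!is.null(config$model)) {
      sflt_model(config$model)
    } else {
      params_model(params)
    }
  }
  switch(command,
    simulate = {
      scenario <- if (is.null(config$scenario)) "constitutive" else
        config$scenario
      cfg <- scenario_config(scenario, duration = config$duration)
      traj <- if (scenario == "constitutive") {
        simulate_constitutive(params, model, cfg)
      } else {
        simulate_pulse_chase(params, model, cfg)
      }
      add(export_trajectory(traj, file.path(out_dir, "trajectory.csv")))
    },
    synth = {
      design <- synthetic_design(
        template = config$template,
        noise_cv = if (is.null(config$noise_cv)) 0.10 else
          config$noise_cv,
        replicates = if (is.null(config$replicates)) 3 else
          config$replicates,
        seed = .stage_seed(seed, paste0("synth_", config$template)))
      ds <- generate_dataset(params, design, model)
      add(write_dataset(ds, file.path(out_dir, "dataset.csv")))
      add(file.path(out_dir, "dataset.yaml"))
    },
    fit = {
      datasets <- .cfg_datasets(config)
      model <- sflt_model(if (is.null(config$model)) "M2" else
        config$model)
      ens <- fit_multistart(model, datasets, .cfg_fit(config, seed))
      add(export_ensemble(ens, file.path(out_dir, "ensemble.csv"),
                          file.path(out_dir, "fit_summary.json")))
      add(file.path(out_dir, "fit_summary.json"))
    },
    `compare-models` = {
      datasets <- .cfg_datasets(config)
      cmp <- compare_models(datasets, .cfg_fit(config, seed))
      add(export_comparison(cmp, file.path(out_dir,
                                           "model_comparison.csv")))
    },
    sensitivity = {
      loc <- local_sensitivity(params, model)
      p1 <- file.path(out_dir, "local_sensitivity.csv")
      utils::write.csv(loc, p1, row.names = FALSE)
      add(p1)
      glob <- global_sensitivity(params, model)
      p2 <- file.path(out_dir, "global_sensitivity.csv")
      utils::write.csv(glob, p2, row.names = FALSE)
      add(p2)
    },
    fluxes = {
      scenario <- if (is.null(config$scenario)) "constitutive" else
        config$scenario
      traj <- if (scenario == "constitutive") {
        simulate_constitutive(params, model)
      } else {
        simulate_pulse_chase(params, model)
      }
      fx <- fluxes(traj)
      p <- file.path(out_dir, "fluxes.csv")
      utils::write.csv(fx, p, row.names = FALSE)
      add(p)
    },
    inhibit = {
      inh <- inhibition_spec(config$target, config$fraction, config$mode)
      control <- simulate_constitutive(params, model)
      traj <- simulate_inhibited(params, inh, model)
      add(export_trajectory(traj, file.path(out_dir, "inhibited.csv")))
      fc <- fold_changes(traj, control)
      p <- file.path(out_dir, "fold_changes.csv")
      utils::write.csv(fc, p, row.names = FALSE)
      add(p)
    },
    invert = {
      if (is.null(config$observations) ||
          !file.exists(config$observations)) {
        stop("invert requires an existing 'observations' CSV",
             call. = FALSE)
      }
      obs <- utils::read.csv(config$observations,
                             stringsAsFactors = FALSE)
      verdicts <- lapply(seq_len(nrow(obs)), function(i) {
        inv <- invert_inhibition(obs$fold_change[i], obs$species[i],
                                 obs$time_h[i], obs$target[i],
                                 obs$mode[i], params, model)
        list(species = obs$species[i], time_h = obs$time_h[i],
             target = obs$target[i], mode = obs$mode[i],
             observed = obs$fold_change[i], feasible = inv$feasible,
             f = inv$f, verdict = inv$verdict)
      })
      p <- file.path(out_dir, "inversion.json")
      jsonlite::write_json(verdicts, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      add(p)
    },
    recover = {
      templates <- if (is.null(config$templates)) {
        c("hornig_like", "kinghorn_like", "jung_like")
      } else {
        config$templates
      }
      noise_cv <- if (is.null(config$noise_cv)) 0 else config$noise_cv
      designs <- lapply(templates, function(tm) {
        synthetic_design(tm, noise_cv = noise_cv,
                         seed = .stage_seed(seed, paste0("synth_", tm)))
      })
      rec <- recovery_experiment(params, designs,
                                 .cfg_fit(config, seed), model)
      p <- file.path(out_dir, "recovery.json")
      jsonlite::write_json(
        list(generating = as.list(unclass(params)),
             errors = rec$errors,
             n_accepted = sum(rec$ensemble$results$accepted)),
        p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      add(p)
    },
    stop("unknown command '", command, "'", call. = FALSE)
  )
  .write_manifest(out_dir, command, config, seed, artifacts)
  invisible(artifacts)
}
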