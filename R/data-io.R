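# Avogadro constant (1/mol), used for #/cell -> concentration conversion
.AVOGADRO <- 6.02214076e23

#' Construct an experimental-style sFLT1 dataset
#'
#' Container for observed time courses of intracellular (I) and/or
#' extracellular (X) sFLT1 from one experiment, together with the metadata
#' needed to compare simulations against it: the scenario, the measurement
#' units, normalization anchors for relative (Western-blot-like) data and
#' the #/cell-to-concentration conversion constants for absolute
#' (ELISA-like) data.
#'
#' @param name Dataset label.
#' @param scenario `"constitutive"` or `"pulse_chase"`.
#' @param observations Data frame with columns `time_h`, `species`
#'   (`"I"`/`"X"`), `value`, and optionally `replicate` (default 1) and
#'   `excluded` (logical, default FALSE).
#' @param units `"absolute_concentration"` (e.g. ng/mL) or `"relative"`.
#' @param anchor_time_X,anchor_time_I Normalization anchor times (h);
#'   required for each species present when `units = "relative"`.
#' @param conversion For absolute units: list with `cells_per_volume`
#'   (cells/mL) and `molar_mass` (g/mol), mapping #/cell to ng/mL.
#' @return A list of class `"sflt_dataset"`.
#' @export
new_dataset <- function(name, scenario = c("constitutive", "pulse_chase"),
                        observations, units = c("relative",
                                                "absolute_concentration"),
                        anchor_time_X = NULL, anchor_time_I = NULL,
                        conversion = NULL) {
  scenario <- match.arg(scenario)
  units <- match.arg(units)
  obs <- as.data.frame(observations)
  required <- c("time_h", "species", "value")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    stop("observations lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(obs)) stop("empty dataset: no observations", call. = FALSE)
  if (is.null(obs$replicate)) obs$replicate <- 1L
  if (is.null(obs$excluded)) obs$excluded <- FALSE
  obs$excluded <- as.logical(obs$excluded)
  bad <- which(!obs$species %in% c("I", "X"))
  if (length(bad)) {
    stop("unknown species in rows ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(obs$value) | obs$value < 0)
  if (length(bad)) {
    stop("non-finite or negative values in rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(obs$time_h) | obs$time_h < 0)
  if (length(bad)) {
    stop("invalid times in rows ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  species <- sort(unique(obs$species))
  if (units == "relative") {
    if ("X" %in% species && is.null(anchor_time_X)) {
      stop("relative dataset with X requires anchor_time_X",
           call. = FALSE)
    }
    if ("I" %in% species && is.null(anchor_time_I)) {
      stop("relative dataset with I requires anchor_time_I",
           call. = FALSE)
    }
  } else if (!is.null(conversion)) {
    stopifnot(is.numeric(conversion$cells_per_volume),
              is.numeric(conversion$molar_mass))
  }
  structure(list(name = name, scenario = scenario,
                 observations = obs[, c("time_h", "species", "value",
                                        "replicate", "excluded")],
                 units = units, anchor_time_X = anchor_time_X,
                 anchor_time_I = anchor_time_I, conversion = conversion,
                 preprocessed = FALSE),
            class = "sflt_dataset")
}

#' @export
print.sflt_dataset <- function(x, ...) {
  cat("sFLT1 dataset '", x$name, "' (", x$scenario, ", ", x$units, ")\n",
      sep = "")
  cat("  ", nrow(x$observations), " observations of ",
      paste(sort(unique(x$observations$species)), collapse = ", "),
      if (x$preprocessed) " (preprocessed)", "\n", sep = "")
  invisible(x)
}

#' Read a dataset from CSV plus metadata sidecar
#'
#' The CSV holds columns `time_h, species, value` and optionally
#' `replicate, excluded`. Metadata (name, scenario, units, anchors,
#' conversion constants) live in a sidecar file with the same stem and a
#' `.yaml`/`.yml`/`.json` extension. Malformed rows are reported with
#' their line numbers.
#'
#' @param path Path to the CSV file.
#' @return An [new_dataset()] object.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(obs)) stop("empty dataset file: ", path, call. = FALSE)
  stem <- sub("\\.csv$", "", path, ignore.case = TRUE)
  side <- paste0(stem, c(".yaml", ".yml", ".json"))
  side <- side[file.exists(side)][1]
  if (is.na(side)) {
    stop("no metadata sidecar (.yaml/.yml/.json) found for ", path,
         call. = FALSE)
  }
  meta <- if (grepl("\\.json$", side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(side)
  }
  new_dataset(name = meta$name, scenario = meta$scenario,
              observations = obs, units = meta$units,
              anchor_time_X = meta$anchor_time_X,
              anchor_time_I = meta$anchor_time_I,
              conversion = meta$conversion)
}

#' Write a dataset to CSV plus metadata sidecar
#'
#' @param dataset An `"sflt_dataset"`.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.yaml` extension.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sflt_dataset"))
  utils::write.csv(dataset$observations, path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(name = dataset$name, scenario = dataset$scenario,
               units = dataset$units,
               anchor_time_X = dataset$anchor_time_X,
               anchor_time_I = dataset$anchor_time_I,
               conversion = dataset$conversion)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  yaml::write_yaml(meta, paste0(sub("\\.csv$", "", path,
                                    ignore.case = TRUE), ".yaml"))
  invisible(path)
}

#' Preprocess a dataset for fitting
#'
#' Drops points flagged as excluded, collapses replicates to per-time-point
#' means, and orders observations deterministically by (species, time).
#' Idempotent.
#'
#' @param dataset An `"sflt_dataset"`.
#' @return The preprocessed dataset (replicate column collapsed to the
#'   replicate count used for each mean).
#' @export
preprocess_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "sflt_dataset"))
  if (isTRUE(dataset$preprocessed)) return(dataset)
  obs <- dataset$observations
  obs <- obs[!obs$excluded, , drop = FALSE]
  if (!nrow(obs)) {
    stop("all observations excluded in dataset '", dataset$name, "'",
         call. = FALSE)
  }
  agg <- stats::aggregate(value ~ species + time_h, data = obs, FUN = mean)
  nrep <- stats::aggregate(value ~ species + time_h, data = obs,
                           FUN = length)
  agg$replicate <- nrep$value
  agg$excluded <- FALSE
  agg <- agg[order(agg$species, agg$time_h),
             c("time_h", "species", "value", "replicate", "excluded")]
  rownames(agg) <- NULL
  out <- dataset
  out$observations <- agg
  out$preprocessed <- TRUE
  out
}

#' Convert a simulated trajectory into a dataset's measurement units
#'
#' Simulations are in #/cell; measurements are either relative (simulated
#' series divided by its value at the dataset's anchor time) or absolute
#' concentrations (#/cell \eqn{\times} cells_per_volume \eqn{\times}
#' molar_mass / Avogadro, reported in ng/mL). Predictions are evaluated at
#' the dataset's observation times by linear interpolation on the
#' reporting grid.
#'
#' @param traj An `"sflt_trajectory"` in #/cell covering the dataset's
#'   time points (and anchors).
#' @param dataset An `"sflt_dataset"`.
#' @return Data frame `time_h, species, predicted, units`.
#' @export
predict_in_dataset_units <- function(traj, dataset) {
  stopifnot(inherits(traj, "sflt_trajectory"),
            inherits(dataset, "sflt_dataset"))
  obs <- dataset$observations
  pred <- numeric(nrow(obs))
  if (dataset$units == "relative") {
    anchors <- list(X = dataset$anchor_time_X, I = dataset$anchor_time_I)
    for (sp in unique(obs$species)) {
      a <- anchors[[sp]]
      if (is.null(a)) {
        stop("no anchor time for species ", sp, call. = FALSE)
      }
      a_val <- trajectory_values(traj, a, sp)
      if (a_val <= 0) stop("zero anchor value for ", sp, call. = FALSE)
      sel <- obs$species == sp
      pred[sel] <- trajectory_values(traj, obs$time_h[sel], sp) / a_val
    }
    units <- "relative"
  } else {
    conv <- dataset$conversion
    if (is.null(conv)) {
      stop("absolute-unit dataset '", dataset$name,
           "' lacks conversion constants", call. = FALSE)
    }
    # #/cell * cells/mL * g/mol / (1/mol) * 1e9 ng/g -> ng/mL
    factor <- conv$cells_per_volume * conv$molar_mass / .AVOGADRO * 1e9
    for (sp in unique(obs$species)) {
      sel <- obs$species == sp
      pred[sel] <- trajectory_values(traj, obs$time_h[sel], sp) * factor
    }
    units <- "ng/mL"
  }
  data.frame(time_h = obs$time_h, species = obs$species, predicted = pred,
             units = units, stringsAsFactors = FALSE)
}
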