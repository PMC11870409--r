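#' Corrected Akaike Information Criterion for a least-squares fit
#'
#' \deqn{AIC_C = n \ln(C/n) + 2k + \frac{2k(k+1)}{n-k-1}}
#' where `C` is the sum-of-squares cost, `n` the number of data points and
#' `k` the degrees of freedom (number of fitted parameters + 1). Natural
#' logarithm; the last term is the small-sample correction, undefined for
#' `n <= k + 1`.
#'
#' @param C Cost (sum of squared residuals), > 0.
#' @param n Number of observations.
#' @param k Degrees of freedom (parameter count + 1).
#' @return The AICc score.
#' @export
#' @examples
#' aicc(C = 10, n = 10, k = 5) # unit mean square: 2k + correction
aicc <- function(C, n, k) {
  if (C <= 0) stop("cost must be > 0 for AICc", call. = FALSE)
  if (n <= k + 1) {
    stop("small-sample correction undefined for n <= k + 1",
         call. = FALSE)
  }
  n * log(C / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and score all candidate models on the same datasets
#'
#' Fits each candidate model by multistart least squares and scores it by
#' cost and AICc (degrees of freedom = active parameters + 1). Larger
#' models additionally receive warm starts at the best fits of each
#' sub-model, with the added process parameter at its nesting value
#' (tau = 0, epsilon = 0, or kappa at its upper bound, since absent
#' production decay is the large-kappa limit), so that the cost of a
#' model essentially never exceeds the cost of any model nested inside it
#' (up to optimizer monotonicity and the finite kappa bound). Also
#' reports, for every (model, addable process) pair, the cost reduction
#' achieved by adding that process.
#'
#' @param datasets List of `"sflt_dataset"` objects.
#' @param cfg A [fit_config()]; `n_starts` applies per model.
#' @param models Character vector of model ids to compare (default all 8).
#' @return A list of class `"sflt_model_comparison"`: `scores` (one row
#'   per model: processes, k, n, cost, per-dataset costs, aicc),
#'   `edges` (cost reduction per process addition), `ensembles` (the fit
#'   ensembles, named by model id).
#' @export
compare_models <- function(datasets, cfg = fit_config(n_starts = 8),
                           models = paste0("M", 1:8)) {
  if (inherits(datasets, "sflt_dataset")) datasets <- list(datasets)
  datasets <- lapply(datasets, function(d) {
    if (d$preprocessed) d else preprocess_dataset(d)
  })
  specs <- lapply(models, sflt_model)
  names(specs) <- models
  n_procs <- vapply(specs, function(m) {
    m$has_delay + m$has_production_decay + m$has_internalization
  }, numeric(1))
  order_idx <- order(n_procs)
  ensembles <- list()
  flags <- c("has_delay", "has_production_decay", "has_internalization")
  proc_param <- c(has_delay = "tau", has_production_decay = "kappa",
                  has_internalization = "epsilon")
  sub_of <- function(m) {
    # model ids obtained by removing one process from m
    out <- character(0)
    for (fl in flags) {
      if (m[[fl]]) {
        args <- stats::setNames(as.list(unlist(m[flags])), flags)
        args[[fl]] <- FALSE
        out <- c(out, do.call(sflt_model, args)$model_id)
      }
    }
    out
  }
  for (id in models[order_idx]) {
    m <- specs[[id]]
    warm <- list()
    for (sub_id in intersect(sub_of(m), names(ensembles))) {
      sub_m <- sflt_model(sub_id)
      best <- ensemble_params(ensembles[[sub_id]], "best")[[1]]
      vals <- unclass(best)
      if (m$has_production_decay && !sub_m$has_production_decay) {
        vals["kappa"] <- cfg$bounds$kappa[2]
      }
      warm <- c(warm, list(do.call(sflt_params, as.list(vals))))
    }
    ensembles[[id]] <- fit_multistart(m, datasets, cfg,
                                      extra_starts = warm)
  }
  n <- ensembles[[1]]$n_obs
  score_rows <- lapply(models, function(id) {
    ens <- ensembles[[id]]
    m <- specs[[id]]
    k <- length(active_parameters(m)) + 1
    conv <- ens$results[ens$results$converged, , drop = FALSE]
    best <- conv[which.min(conv$cost), , drop = FALSE]
    cost <- best$cost
    score <- if (cost > 0 && n > k + 1) aicc(cost, n, k) else NA_real_
    per_ds <- best[, grep("^cost_", names(best)), drop = FALSE]
    cbind(data.frame(model_id = id, has_delay = m$has_delay,
                     has_production_decay = m$has_production_decay,
                     has_internalization = m$has_internalization,
                     k = k, n = n, cost = cost, aicc = score),
          per_ds)
  })
  scores <- do.call(rbind, score_rows)
  edge_rows <- list()
  for (id in models) {
    m <- specs[[id]]
    for (fl in flags) {
      if (!m[[fl]]) {
        args <- stats::setNames(as.list(unlist(m[flags])), flags)
        args[[fl]] <- TRUE
        to_id <- do.call(sflt_model, args)$model_id
        if (to_id %in% models) {
          edge_rows[[length(edge_rows) + 1]] <- data.frame(
            from = id, to = to_id, process = proc_param[[fl]],
            delta_cost = scores$cost[scores$model_id == id] -
              scores$cost[scores$model_id == to_id])
        }
      }
    }
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else NULL
  structure(list(scores = scores, edges = edges, ensembles = ensembles),
            class = "sflt_model_comparison")
}

#' @export
print.sflt_model_comparison <- function(x, ...) {
  cat("Candidate-model comparison (", x$scores$n[1], " observations)\n",
      sep = "")
  print(x$scores[, c("model_id", "k", "cost", "aicc")], row.names = FALSE)
  best <- x$scores$model_id[which.min(x$scores$aicc)]
  cat("lowest AICc:", best, "\n")
  invisible(x)
}

#' Export a model comparison table to CSV
#'
#' @param comparison An `"sflt_model_comparison"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_comparison <- function(comparison, path) {
  utils::write.csv(comparison$scores, path, row.names = FALSE)
  invisible(path)
}
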