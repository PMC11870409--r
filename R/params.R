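#' Kinetic parameter set for the sFLT1 trafficking models
#'
#' Bundles the rate parameters of one model instance. All parameters are
#' non-negative; parameters of processes absent from the paired model
#' structure (see [sflt_model()]) are stored as exact zeros, so a single
#' rate-term implementation serves all eight candidate models.
#'
#' @param alpha Production rate of intracellular sFLT1 (#/cell/h).
#' @param beta Secretion rate constant, intracellular to extracellular (1/h).
#' @param gamma Intracellular degradation rate constant (1/h).
#' @param delta Extracellular degradation rate constant (1/h).
#' @param tau Maturation delay between synthesis and eligibility for
#'   secretion or intracellular degradation (h). 0 when the delay process
#'   is absent.
#' @param epsilon Internalization rate constant, extracellular to
#'   intracellular (1/h). 0 when the process is absent.
#' @param kappa Production decay rate constant applied during the chase
#'   phase of pulse-chase experiments (1/h). 0 when the process is absent.
#'
#' @return A named numeric vector of class `"sflt_params"`.
#' @seealso [sflt_model()], [steady_state()], [compound_constants()]
#' @export
#' @examples
#' p <- sflt_params(alpha = 1.4e5, beta = 0.05, gamma = 0.12, delta = 0.057,
#'                  tau = 2)
#' steady_state(p)
sflt_params <- function(alpha, beta, gamma, delta, tau = 0, epsilon = 0,
                        kappa = 0) {
  p <- c(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), delta = as.numeric(delta),
         tau = as.numeric(tau), epsilon = as.numeric(epsilon),
         kappa = as.numeric(kappa))
  if (anyNA(p) || any(!is.finite(p))) {
    stop("all parameters must be finite numbers", call. = FALSE)
  }
  if (any(p < 0)) {
    stop("all parameters must be non-negative; got negative ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  }
  structure(p, class = "sflt_params")
}

#' @export
print.sflt_params <- function(x, ...) {
  cat("sFLT1 kinetic parameters:\n")
  u <- c(alpha = "#/cell/h", beta = "1/h", gamma = "1/h", delta = "1/h",
         tau = "h", epsilon = "1/h", kappa = "1/h")
  for (nm in names(u)) {
    cat(sprintf("  %-8s %-12g %s\n", nm, unclass(x)[[nm]], u[[nm]]))
  }
  invisible(x)
}

.PARAM_NAMES <- c("alpha", "beta", "gamma", "delta", "tau", "epsilon",
                  "kappa")

# model_id is a bijection with the three optional-process flags:
# the three bits (delay, production decay, internalization) in binary order.
.MODEL_TABLE <- data.frame(
  model_id = paste0("M", 1:8),
  has_delay = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
  has_production_decay = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                           TRUE),
  has_internalization = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                          TRUE),
  stringsAsFactors = FALSE
)

#' Candidate model structures M1-M8
#'
#' The eight candidate models combine a core
#' production/secretion/degradation skeleton with any subset of three
#' optional processes: a maturation delay \eqn{\tau} (secretion and
#' intracellular degradation act on \eqn{I(t-\tau)}), first-order
#' internalization of extracellular sFLT1 (rate constant \eqn{\epsilon}),
#' and exponential decay of production during the chase phase of
#' pulse-chase experiments (rate constant \eqn{\kappa}). M1 has all three
#' absent (a plain ODE model); M2 adds only the maturation delay (the base
#' DDE model). The remaining labels follow binary order over the flags
#' (delay, production decay, internalization): M3 = production decay only,
#' M4 = internalization only, M5 = delay + production decay,
#' M6 = delay + internalization, M7 = production decay + internalization,
#' M8 = all three.
#'
#' @param model_id One of `"M1"`..`"M8"`, or `NULL` to specify flags
#'   directly.
#' @param has_delay,has_production_decay,has_internalization Logical flags;
#'   used (and required to match) when `model_id` is given, or looked up to
#'   find the label when it is not.
#'
#' @return A list of class `"sflt_model"` with the three flags and the
#'   `model_id` label.
#' @export
#' @examples
#' sflt_model("M2")
#' sflt_model(has_delay = TRUE, has_internalization = TRUE)
sflt_model <- function(model_id = NULL, has_delay = NULL,
                       has_production_decay = NULL,
                       has_internalization = NULL) {
  if (!is.null(model_id)) {
    row <- .MODEL_TABLE[.MODEL_TABLE$model_id == model_id, ]
    if (nrow(row) != 1) {
      stop("unknown model_id '", model_id, "'; expected M1..M8",
           call. = FALSE)
    }
    for (fl in c("has_delay", "has_production_decay",
                 "has_internalization")) {
      given <- get(fl)
      if (!is.null(given) && !identical(as.logical(given), row[[fl]])) {
        stop("flag ", fl, " contradicts model_id ", model_id,
             call. = FALSE)
      }
    }
  } else {
    flags <- c(isTRUE(has_delay), isTRUE(has_production_decay),
               isTRUE(has_internalization))
    row <- .MODEL_TABLE[.MODEL_TABLE$has_delay == flags[1] &
                          .MODEL_TABLE$has_production_decay == flags[2] &
                          .MODEL_TABLE$has_internalization == flags[3], ]
  }
  structure(list(model_id = row$model_id,
                 has_delay = row$has_delay,
                 has_production_decay = row$has_production_decay,
                 has_internalization = row$has_internalization),
            class = "sflt_model")
}

#' @export
print.sflt_model <- function(x, ...) {
  onoff <- function(b) if (b) "present" else "absent"
  cat("sFLT1 candidate model ", x$model_id, "\n",
      "  maturation delay (tau):      ", onoff(x$has_delay), "\n",
      "  production decay (kappa):    ", onoff(x$has_production_decay),
      "\n",
      "  internalization (epsilon):   ", onoff(x$has_internalization),
      "\n", sep = "")
  invisible(x)
}

#' Parameters active in a candidate model
#'
#' The core parameters alpha, beta, gamma, delta are present in every
#' model; tau, kappa and epsilon are active only when the corresponding
#' optional process is part of the model structure.
#'
#' @param model An [sflt_model()].
#' @return Character vector of active parameter names.
#' @export
active_parameters <- function(model) {
  stopifnot(inherits(model, "sflt_model"))
  c("alpha", "beta", "gamma", "delta",
    if (model$has_delay) "tau",
    if (model$has_production_decay) "kappa",
    if (model$has_internalization) "epsilon")
}

#' Check that a parameter set is consistent with a model structure
#'
#' Parameters of absent processes must be exactly zero.
#'
#' @param params An [sflt_params()] set.
#' @param model An [sflt_model()].
#' @return `params`, invisibly, if consistent; otherwise an error.
#' @export
check_params <- function(params, model) {
  stopifnot(inherits(params, "sflt_params"), inherits(model, "sflt_model"))
  inactive <- setdiff(.PARAM_NAMES, active_parameters(model))
  bad <- inactive[unclass(params)[inactive] != 0]
  if (length(bad)) {
    stop("parameters ", paste(bad, collapse = ", "),
         " must be 0 for model ", model$model_id, call. = FALSE)
  }
  invisible(params)
}

#' Reference parameter set for HUVEC sFLT1 secretion
#'
#' The packaged reference values are the component-wise medians of an
#' ensemble of accepted least-squares fits of the maturation-delay model
#' (M2) to constitutive-secretion and pulse-chase time courses measured in
#' human umbilical vein endothelial cells. They serve as the default
#' baseline for sensitivity and perturbation analyses and as the
#' generating truth for the packaged synthetic datasets.
#'
#' @return An [sflt_params()] set with attribute `"model"` set to the M2
#'   model structure.
#' @export
#' @examples
#' p <- reference_params()
#' compound_constants(p)
reference_params <- function() {
  path <- system.file("extdata", "reference_params.yaml",
                      package = "sflt1sim", mustWork = TRUE)
  read_params(path)
}

#' Read or write a parameter set as a flat key-value file
#'
#' Parameter sets (with their model label) serialize to a flat YAML or
#' JSON mapping, chosen by file extension. Fields: `model_id` plus one key
#' per parameter; absent parameters may be omitted and default to 0.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param params An [sflt_params()] set.
#' @param model An [sflt_model()]; defaults to the `"model"` attribute of
#'   `params` or, failing that, a structure inferred from which optional
#'   parameters are non-zero.
#' @return `read_params()` returns an [sflt_params()] with attribute
#'   `"model"`; `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  p <- sflt_params(alpha = vals$alpha, beta = vals$beta, gamma = vals$gamma,
                   delta = vals$delta,
                   tau = if (is.null(vals$tau)) 0 else vals$tau,
                   epsilon = if (is.null(vals$epsilon)) 0 else vals$epsilon,
                   kappa = if (is.null(vals$kappa)) 0 else vals$kappa)
  model <- if (!is.null(vals$model_id)) {
    sflt_model(vals$model_id)
  } else {
    sflt_model(has_delay = p[["tau"]] > 0,
               has_production_decay = p[["kappa"]] > 0,
               has_internalization = p[["epsilon"]] > 0)
  }
  check_params(p, model)
  attr(p, "model") <- model
  p
}

#' @rdname read_params
#' @export
write_params <- function(params, path, model = NULL) {
  stopifnot(inherits(params, "sflt_params"))
  if (is.null(model)) model <- attr(params, "model")
  out <- as.list(unclass(params))
  if (!is.null(model)) out <- c(list(model_id = model$model_id), out)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Model structure paired with a parameter set
#'
#' Returns the `"model"` attribute of the parameter set if present,
#' otherwise infers the structure from which optional parameters are
#' non-zero.
#'
#' @param params An [sflt_params()] set.
#' @return An [sflt_model()].
#' @export
params_model <- function(params) {
  m <- attr(params, "model")
  if (!is.null(m)) return(m)
  sflt_model(has_delay = params[["tau"]] > 0,
             has_production_decay = params[["kappa"]] > 0,
             has_internalization = params[["epsilon"]] > 0)
}
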