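#' Instantaneous rate terms of the trafficking equations
#'
#' Evaluates the right-hand side of the candidate model equations at one
#' state. The equations are assembled piecewise from the processes present
#' in the model structure:
#' \deqn{dI/dt = production - \beta I_d - \gamma I_d + \epsilon X}
#' \deqn{dX/dt = \beta I_d - \delta X - \epsilon X}
#' where \eqn{I_d} is the intracellular level at the delayed time
#' \eqn{t-\tau} when the maturation delay is present, and at \eqn{t}
#' otherwise. The production term is \eqn{\alpha} during pre-simulation,
#' pulse and constitutive phases; during the chase phase it is
#' \eqn{\alpha e^{-\kappa t_c}} (with \eqn{t_c} the time since the media
#' change) when production decay is part of the model, and 0 otherwise.
#'
#' @param state Named list or vector with elements `I`, `X` (and optionally
#'   `t`), in #/cell.
#' @param delayed_I Intracellular sFLT1 at the delayed time `t - tau`
#'   (#/cell); pass the current `I` for models without the delay.
#' @param params An [sflt_params()] set.
#' @param model An [sflt_model()] structure.
#' @param phase One of `"presim"`, `"pulse"`, `"chase"`, `"constitutive"`.
#' @param t_since_chase Time since the media change (h); required in the
#'   chase phase when production decay is present.
#'
#' @return Named numeric vector `c(dI = ..., dX = ...)` in #/cell/h.
#' @export
#' @examples
#' p <- reference_params()
#' rate_terms(list(I = 0, X = 0), delayed_I = 0, p, sflt_model("M2"),
#'            phase = "constitutive")
rate_terms <- function(state, delayed_I, params, model,
                       phase = c("constitutive", "presim", "pulse",
                                 "chase"),
                       t_since_chase = NULL) {
  phase <- match.arg(phase)
  check_params(params, model)
  I <- state[["I"]]
  X <- state[["X"]]
  if (I < 0 || X < 0 || delayed_I < 0) {
    stop("state and delayed_I must be non-negative", call. = FALSE)
  }
  p <- unclass(params)
  Id <- if (model$has_delay) delayed_I else I
  prod <- if (phase == "chase") {
    if (model$has_production_decay) {
      if (is.null(t_since_chase)) {
        stop("t_since_chase required in chase phase with production decay",
             call. = FALSE)
      }
      p[["alpha"]] * exp(-p[["kappa"]] * t_since_chase)
    } else {
      0
    }
  } else {
    p[["alpha"]]
  }
  dI <- prod - (p[["beta"]] + p[["gamma"]]) * Id + p[["epsilon"]] * X
  dX <- p[["beta"]] * Id - p[["delta"]] * X - p[["epsilon"]] * X
  c(dI = dI, dX = dX)
}

#' Theoretical steady state and half-times under constitutive production
#'
#' Closed-form steady state of the trafficking equations with constant
#' production. For models without internalization,
#' \deqn{I_{SS} = \alpha/(\beta+\gamma), \quad
#'       X_{SS} = \alpha\beta / (\delta(\beta+\gamma))}
#' and the characteristic times to half-maximal levels are
#' \eqn{T_{50,I} = \ln 2/(\beta+\gamma)} and
#' \eqn{T_{50,X} = \ln 2/\delta}, assuming first-order removal kinetics.
#' With internalization present the steady state generalizes to
#' \eqn{I_{SS} = \alpha(\delta+\epsilon) / (\delta(\beta+\gamma) +
#' \gamma\epsilon)} and \eqn{X_{SS} = \alpha\beta / (\delta(\beta+\gamma) +
#' \gamma\epsilon)}; the reported half-times still use the simple
#' first-order expressions. The maturation delay does not alter the steady
#' state, because \eqn{I(t-\tau) = I(t)} there.
#'
#' @param params An [sflt_params()] set with `beta + gamma > 0` and
#'   `delta > 0`.
#' @return A list with `I_SS`, `X_SS` (#/cell), `T50_I`, `T50_X` (h).
#' @export
#' @examples
#' steady_state(reference_params())
steady_state <- function(params) {
  stopifnot(inherits(params, "sflt_params"))
  p <- unclass(params)
  c2 <- p[["beta"]] + p[["gamma"]]
  if (c2 <= 0) {
    stop("degenerate parameters: beta + gamma must be > 0", call. = FALSE)
  }
  if (p[["delta"]] <= 0) {
    stop("degenerate parameters: delta must be > 0", call. = FALSE)
  }
  den <- p[["delta"]] * c2 + p[["gamma"]] * p[["epsilon"]]
  I_SS <- p[["alpha"]] * (p[["delta"]] + p[["epsilon"]]) / den
  X_SS <- p[["alpha"]] * p[["beta"]] / den
  list(I_SS = I_SS, X_SS = X_SS,
       T50_I = log(2) / c2, T50_X = log(2) / p[["delta"]])
}

#' Compound constants c1 and c2
#'
#' The fitted ensembles constrain the product \eqn{c_1 = \alpha\beta}
#' (#/cell/h^2) and the sum \eqn{c_2 = \beta + \gamma} (1/h) much more
#' tightly than the individual parameters. In terms of these constants the
#' steady states read \eqn{I_{SS} = \alpha/c_2} and
#' \eqn{X_{SS} = c_1/(\delta c_2)}.
#'
#' @param params An [sflt_params()] set.
#' @return A list with `c1` and `c2`.
#' @export
compound_constants <- function(params) {
  stopifnot(inherits(params, "sflt_params"))
  p <- unclass(params)
  list(c1 = p[["alpha"]] * p[["beta"]],
       c2 = p[["beta"]] + p[["gamma"]])
}

#' Construct a parameter set from the compound-constant constraints
#'
#' Given fixed compound constants `c1`, `c2` and fixed `delta`, `tau`, the
#' remaining degree of freedom is resolved by choosing the secretion rate
#' constant: \eqn{\alpha = c_1/\beta} and \eqn{\gamma = c_2 - \beta}.
#' Used to span the family of parameter sets consistent with the fitted
#' time-course data (e.g. \eqn{\beta \in \{0.2, 0.4, 0.6, 0.8, 1\} c_2}).
#'
#' @param beta Secretion rate constant (1/h); must satisfy
#'   `0 < beta <= c2`.
#' @param c1 Compound constant \eqn{\alpha\beta} (#/cell/h^2).
#' @param c2 Compound constant \eqn{\beta+\gamma} (1/h).
#' @param delta Extracellular degradation rate constant (1/h).
#' @param tau Maturation delay (h).
#' @return An [sflt_params()] set satisfying the constraints exactly.
#' @export
#' @examples
#' cc <- compound_constants(reference_params())
#' params_from_beta(0.5 * cc$c2, cc$c1, cc$c2, delta = 0.0574, tau = 1.96)
params_from_beta <- function(beta, c1, c2, delta, tau = 0) {
  if (beta <= 0 || beta > c2) {
    stop("constraint violation: beta must satisfy 0 < beta <= c2",
         call. = FALSE)
  }
  sflt_params(alpha = c1 / beta, beta = beta, gamma = c2 - beta,
              delta = delta, tau = tau)
}

#' Theoretical bounds implied by the compound constants
#'
#' With \eqn{c_1 = \alpha\beta} and \eqn{c_2 = \beta+\gamma} fixed, the
#' family of consistent parameter sets obeys
#' \eqn{I_{SS} \ge c_1/c_2^2}, \eqn{\alpha \ge c_1/c_2}, and
#' \eqn{\beta, \gamma \le c_2}.
#'
#' @param c1,c2 Compound constants (both > 0), or a list with elements
#'   `c1`, `c2` as returned by [compound_constants()] passed as `c1`.
#' @return A list with `min_I_SS`, `min_alpha`, `max_beta`, `max_gamma`.
#' @export
theoretical_bounds <- function(c1, c2 = NULL) {
  if (is.list(c1)) {
    c2 <- c1$c2
    c1 <- c1$c1
  }
  stopifnot(c1 > 0, c2 > 0)
  list(min_I_SS = c1 / c2^2, min_alpha = c1 / c2,
       max_beta = c2, max_gamma = c2)
}
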