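#' Least-squares fitness of a parameter vector
#'
#' The quantity every optimizer in this package minimizes: the unweighted
#' residual sum of squares between the dataset and the model prediction at
#' the dataset's sampling times, summed over all observed species and time
#' points.  Integration failure yields `Inf`, so failed parameter vectors
#' lose every greedy comparison.
#'
#' @param params numeric parameter vector.
#' @param model an [ode_model()].
#' @param data a `ts_dataset` whose species match the model's observed
#'   species.
#' @param weights optional per-species weights (default all 1).
#' @param initial_state optional replacement initial state (defaults to the
#'   dataset's recorded initial state, falling back to the model's).
#' @return non-negative scalar fitness, or `Inf` on integration failure.
#' @export
evaluate_fitness <- function(params, model, data, weights = NULL,
                             initial_state = NULL) {
  stopifnot(inherits(model, "ode_model"), inherits(data, "ts_dataset"))
  obs_names <- model$state_names[model$observed]
  if (!identical(colnames(data$observations), obs_names))
    stop("dataset species (", paste(colnames(data$observations), collapse = ","),
         ") do not match model observed species (",
         paste(obs_names, collapse = ","), ")")
  if (is.null(initial_state) && !is.null(data$source$initial_state))
    initial_state <- data$source$initial_state
  # negative-concentration warnings are routine for candidate vectors during
  # global search; they matter for reported fits, not for fitness scoring
  pred <- tryCatch(
    suppressWarnings(
      integrate_model(model, params, data$times, initial_state = initial_state)),
    fireflyde_integration_failure = function(e) NULL)
  if (is.null(pred)) return(Inf)
  res2 <- (data$observations - pred$states)^2
  if (!is.null(weights)) {
    stopifnot(length(weights) == ncol(res2))
    res2 <- sweep(res2, 2, weights, `*`)
  }
  sum(res2)
}

#' Build an objective closure with an evaluation counter
#'
#' Returns a function of the free parameters that computes
#' [evaluate_fitness()] with the remaining parameters clamped at
#' `fixed_params`, incrementing a call counter on every evaluation.  The
#' counter is read with [objective_evaluations()].
#'
#' @param model an [ode_model()].
#' @param data a `ts_dataset`.
#' @param free character vector of parameter names to estimate; `NULL` means
#'   all parameters.
#' @param fixed_params full-length parameter vector supplying the clamped
#'   values (defaults to the model's `default_params`); ignored entries for
#'   free parameters.
#' @param weights optional per-species weights.
#' @return a function `f(x)`; attributes of its environment expose the count.
#' @export
make_objective <- function(model, data, free = NULL, fixed_params = NULL,
                           weights = NULL) {
  stopifnot(inherits(model, "ode_model"))
  if (is.null(fixed_params)) fixed_params <- model$default_params
  if (is.null(free)) {
    free_idx <- seq_along(model$param_names)
  } else {
    free_idx <- match(free, model$param_names)
    if (anyNA(free_idx)) stop("unknown free parameter(s): ",
                              paste(free[is.na(free_idx)], collapse = ", "))
    if (is.null(fixed_params))
      stop("fixed_params required when only a subset of parameters is free")
  }
  template <- if (is.null(fixed_params))
    stats::setNames(rep(NA_real_, length(model$param_names)), model$param_names)
  else stats::setNames(as.numeric(fixed_params), model$param_names)
  n_evals <- 0L
  fn <- function(x) {
    full <- template
    full[free_idx] <- x
    n_evals <<- n_evals + 1L
    evaluate_fitness(full, model, data, weights = weights)
  }
  attr(fn, "free_idx") <- free_idx
  attr(fn, "free_names") <- model$param_names[free_idx]
  fn
}

#' @rdname make_objective
#' @param fn a closure produced by [make_objective()].
#' @export
objective_evaluations <- function(fn) {
  environment(fn)$n_evals
}
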