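#' Define an ODE model
#'
#' An `ode_model` bundles everything the estimation pipeline needs to know
#' about a dynamical system: the state labels, the parameter labels, the
#' right-hand side, default initial conditions, which states are observed
#' (measured), and per-parameter search bounds.
#'
#' @param name identifier string.
#' @param state_names character vector of species labels.
#' @param param_names character vector of parameter labels (length `M`).
#' @param rhs function `(state, params, t, input)` returning the derivative
#'   vector; must return a finite vector of the same length as `state` for
#'   finite inputs.
#' @param initial_state numeric vector of starting concentrations, one per
#'   state, taken to hold at the first requested sampling time.
#' @param observed integer indices (or state names) of the measured species;
#'   must be a non-empty subset of the states.
#' @param bounds numeric `M x 2` matrix (or 2-column data frame) of
#'   `[lower, upper]` search bounds per parameter.
#' @param default_params optional named numeric vector of reference parameter
#'   values (for the built-in models, the generating set).
#' @param default_times optional numeric vector used as the sampling grid when
#'   the caller does not supply one.
#' @param input optional function of time giving an external input signal;
#'   passed through to `rhs`, unused by the built-in models.
#' @param compiled optional list `(func, initfunc, dllname)` naming compiled
#'   derivative routines used by [integrate_model()] instead of `rhs`.
#'
#' @return An object of class `ode_model`.
#' @seealso [get_model()], [integrate_model()], [apply_perturbation()]
#' @export
ode_model <- function(name, state_names, param_names, rhs, initial_state,
                      observed, bounds, default_params = NULL,
                      default_times = NULL, input = NULL, compiled = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  state_names <- as.character(state_names)
  param_names <- as.character(param_names)
  if (!is.function(rhs)) stop("'rhs' must be a function")
  initial_state <- as.numeric(initial_state)
  if (length(initial_state) != length(state_names))
    stop("initial_state must have one entry per state")
  if (is.character(observed)) observed <- match(observed, state_names)
  observed <- as.integer(observed)
  if (length(observed) == 0L || anyNA(observed) ||
      any(observed < 1L | observed > length(state_names)))
    stop("'observed' must be a non-empty subset of the state indices")
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != length(param_names) || ncol(bounds) != 2L)
    stop("'bounds' must be an M x 2 matrix of [lower, upper]")
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  if (any(bounds[, 1] > bounds[, 2]))
    stop("each lower bound must not exceed its upper bound")
  dimnames(bounds) <- list(param_names, c("lower", "upper"))
  if (!is.null(default_params)) {
    default_params <- as.numeric(default_params)
    if (length(default_params) != length(param_names))
      stop("default_params must have one entry per parameter")
    names(default_params) <- param_names
  }
  names(initial_state) <- state_names
  structure(
    list(name = name, state_names = state_names, param_names = param_names,
         rhs = rhs, initial_state = initial_state, observed = observed,
         bounds = bounds, default_params = default_params,
         default_times = default_times, input = input, compiled = compiled),
    class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, "\n", sep = "")
  cat("  states   : ", paste(x$state_names, collapse = ", "),
      " (observed: ", paste(x$state_names[x$observed], collapse = ", "),
      ")\n", sep = "")
  cat("  params   : ", length(x$param_names), " (",
      paste(utils::head(x$param_names, 6), collapse = ", "),
      if (length(x$param_names) > 6) ", ..." else "", ")\n", sep = "")
  if (!is.null(x$compiled)) cat("  rhs      : compiled (", x$compiled$func, ")\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# built-in right-hand sides (reference R implementations)

#' p53-Mdm2 negative feedback loop derivatives
#'
#' Four-species model of the p53-Mdm2 core loop: nuclear p53 (`A`) is produced
#' at a constant rate and degraded both basally and through its complex with
#' Mdm2; p53 transactivates Mdm2 mRNA (`D`), which is translated into Mdm2
#' (`B`); p53 and Mdm2 reversibly form a complex (`C`) through which
#' Mdm2-mediated p53 degradation proceeds, releasing Mdm2.
#'
#' The parameter roles are: `k1` p53 production, `k2` p53 degradation, `k3`
#' complex formation, `k4` complex dissociation/diffusion, `k5` Mdm2
#' degradation, `k6` Mdm2 translation, `k7` Mdm2-mediated p53 degradation,
#' `k8` Mdm2 transcription, `k9` Mdm2 mRNA degradation.
#'
#' @param state numeric 4-vector `(A, B, C, D)`.
#' @param params numeric 9-vector `k1..k9`, non-negative.
#' @param t time (unused; the system is autonomous).
#' @param input unused, present for interface compatibility.
#' @return named numeric 4-vector of derivatives.
#' @export
p53_rhs <- function(state, params, t = 0, input = NULL) {
  if (length(state) != 4L) stop("p53 model has 4 states")
  if (length(params) != 9L) stop("p53 model has 9 parameters")
  A <- state[[1]]; B <- state[[2]]; C <- state[[3]]; D <- state[[4]]
  k <- unname(params)
  form <- k[3] * A * B
  c(A = k[1] - k[2] * A - form + k[4] * C,
    B = k[6] * D - form + k[4] * C + k[7] * C - k[5] * B,
    C = form - k[4] * C - k[7] * C,
    D = k[8] * A - k[9] * D)
}

# saturable flux with a zero-numerator short-circuit so an all-zero parameter
# vector yields zero flux; a vanishing denominator with non-zero flux is a
# genuine evaluation error and is reported with the parameter vector
.sat_rate <- function(vmax, s, km, inhib = 0, params = NULL) {
  num <- vmax * s
  if (num == 0) return(0)
  den <- km + s + inhib
  if (den == 0)
    stop("zero denominator in saturable rate; params = ",
         paste(signif(params, 6), collapse = ", "))
  num / den
}

#' Arginine catabolism pathway derivatives
#'
#' Three-pool kinetic scheme of endothelial arginine catabolism: external
#' arginine (`A`) enters the cell through a cationic amino-acid carrier that
#' is competitively inhibited by ornithine; internal arginine (`C`) is
#' consumed by arginase I and II (producing ornithine, `B`), by nitric-oxide
#' synthase, by carrier-mediated efflux, and by a first-order
#' protein-synthesis drain; ornithine is consumed by ornithine decarboxylase
#' and ornithine aminotransferase.  Only ornithine and internal arginine are
#' observed.
#'
#' Parameter roles (16 in total): `k1`/`k2` carrier uptake Vmax/Km, `k7`
#' ornithine competitive-inhibition weight on uptake, `k3`/`k4` arginase II
#' Vmax/Km, `k5`/`k6` NOS Vmax/Km, `k8`/`k9` ODC Vmax/Km, `k10`
#' protein-synthesis drain rate, `k11`/`k12` OAT Vmax/Km, `k13`/`k14` carrier
#' efflux Vmax/Km, `k15`/`k16` arginase I Vmax/Km.  Setting `k7 = 0` removes
#' the competitive inhibition by ornithine (the F2 variant).
#'
#' @param state numeric 3-vector `(A, B, C)` = external arginine, ornithine,
#'   internal arginine.
#' @param params numeric 16-vector `k1..k16`, non-negative.
#' @param t time (unused; the system is autonomous).
#' @param input unused, present for interface compatibility.
#' @return named numeric 3-vector of derivatives.
#' @export
arginine_rhs <- function(state, params, t = 0, input = NULL) {
  if (length(state) != 3L) stop("arginine model has 3 states")
  if (length(params) != 16L) stop("arginine model has 16 parameters")
  A <- state[[1]]; B <- state[[2]]; C <- state[[3]]
  k <- unname(params)
  v_up  <- .sat_rate(k[1],  A, k[2],  k[7] * B, params = k)
  v_as2 <- .sat_rate(k[3],  C, k[4],  params = k)
  v_nos <- .sat_rate(k[5],  C, k[6],  params = k)
  v_odc <- .sat_rate(k[8],  B, k[9],  params = k)
  v_oat <- .sat_rate(k[11], B, k[12], params = k)
  v_ef  <- .sat_rate(k[13], C, k[14], params = k)
  v_as1 <- .sat_rate(k[15], C, k[16], params = k)
  c(A = v_ef - v_up,
    B = v_as1 + v_as2 - v_odc - v_oat,
    C = v_up - v_ef - v_as1 - v_as2 - v_nos - k[10] * C)
}

# ---------------------------------------------------------------------------
# registry

.p53_true_params <- c(k1 = 0.5, k2 = 0.05, k3 = 2, k4 = 0.1, k5 = 0.5,
                      k6 = 1.5, k7 = 2, k8 = 0.6, k9 = 0.8)

.arginine_F1 <- c(k1 = 70, k2 = 160.5, k3 = 380, k4 = 847, k5 = 420,
                  k6 = 420, k7 = 110, k8 = 1500, k9 = 1000, k10 = 0.013,
                  k11 = 60, k12 = 1.33, k13 = 16, k14 = 160.5, k15 = 380,
                  k16 = 847)

.variant_overrides <- list(
  p53_E1      = list(base = "p53", overrides = list()),
  p53_E2      = list(base = "p53", overrides = list(k4 = 0, k9 = 0)),
  arginine_F1 = list(base = "arginine", overrides = list()),
  arginine_F2 = list(base = "arginine", overrides = list(k7 = 0)),
  arginine_F3 = list(base = "arginine",
                     overrides = list(k8 = 100, k15 = 1, k16 = 1)),
  arginine_F4 = list(base = "arginine",
                     overrides = list(k7 = 1, k10 = 1, k14 = 1, k15 = 1)),
  arginine_F5 = list(base = "arginine",
                     overrides = list(k2 = 1, k5 = 1, k8 = 1, k15 = 1, k16 = 1))
)

.base_model <- function(which) {
  switch(which,
    p53 = ode_model(
      name = "p53",
      state_names = c("A", "B", "C", "D"),
      param_names = paste0("k", 1:9),
      rhs = p53_rhs,
      initial_state = c(0.2, 0.1, 0, 0),
      observed = 1:4,
      bounds = cbind(rep(0, 9), rep(10, 9)),
      default_params = .p53_true_params,
      default_times = seq(0, 30, length.out = 100),
      compiled = list(func = "p53_derivs", initfunc = "p53_initmod",
                      dllname = "fireflyde")),
    arginine = ode_model(
      name = "arginine",
      state_names = c("A", "B", "C"),
      param_names = paste0("k", 1:16),
      rhs = arginine_rhs,
      initial_state = c(1000, 30, 100),
      observed = c(2L, 3L),
      bounds = cbind(rep(0, 16), rep(2000, 16)),
      default_params = .arginine_F1,
      default_times = seq(0, 5, length.out = 100),
      compiled = list(func = "arginine_derivs", initfunc = "arginine_initmod",
                      dllname = "fireflyde")),
    stop("unknown base model: ", which))
}

#' Built-in model registry
#'
#' `get_model()` returns a built-in model variant by name; `list_models()`
#' returns the available names.  Variants are the base model with parameter
#' overrides applied to `default_params`: `p53_E2` zeroes `k4` and `k9`
#' (no complex dissociation, no Mdm2 mRNA turnover), `arginine_F2` zeroes
#' `k7` (no competitive inhibition by ornithine), and `arginine_F3`/`F4`/`F5`
#' apply the alternative parameter sets used for robustness checks.
#'
#' @param name one of `list_models()`, e.g. `"p53_E1"`, `"arginine_F1"`.
#' @return An [ode_model()] whose `default_params` carry the variant's values.
#' @export
get_model <- function(name) {
  spec <- .variant_overrides[[name]]
  if (is.null(spec))
    stop("unknown model '", name, "'; available: ",
         paste(names(.variant_overrides), collapse = ", "))
  model <- .base_model(spec$base)
  model <- apply_perturbation(model, spec$overrides)
  model$name <- name
  model
}

#' @rdname get_model
#' @export
list_models <- function() names(.variant_overrides)

#' Perturb a model's reference parameters
#'
#' Returns a copy of the model whose `default_params` have the named entries
#' replaced; the input model is not modified.  This is how knockout-style
#' variants are built (e.g. setting a rate to zero removes the corresponding
#' process).
#'
#' @param model an [ode_model()] with `default_params` set.
#' @param overrides named list or vector of parameter values to replace.
#' @return the perturbed `ode_model`.
#' @export
apply_perturbation <- function(model, overrides) {
  stopifnot(inherits(model, "ode_model"))
  overrides <- unlist(overrides)
  if (length(overrides) == 0L) return(model)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("overrides must be named")
  unknown <- setdiff(names(overrides), model$param_names)
  if (length(unknown) > 0L)
    stop("unknown parameter label(s): ", paste(unknown, collapse = ", "))
  if (is.null(model$default_params))
    stop("model has no default_params to perturb")
  model$default_params[names(overrides)] <- as.numeric(overrides)
  model
}

# ---------------------------------------------------------------------------
# integration

#' Integrate a model over a sampling grid
#'
#' Solves the model ODEs with a stiff-capable adaptive solver (`lsoda`) and
#' returns the observed-species values at exactly the requested times.  The
#' initial state holds at the first requested time.  Built-in models use
#' their compiled derivative routines; user models fall back to the R `rhs`.
#'
#' Integration failure (solver error or non-finite output) raises a condition
#' of class `fireflyde_integration_failure` carrying the offending parameter
#' vector; optimizers map this to an infinite fitness.  Concentrations are
#' not constrained to stay non-negative, but an observed value below
#' `-10 * atol` triggers a warning.
#'
#' @param model an [ode_model()].
#' @param params numeric parameter vector (length `M`).
#' @param times strictly increasing numeric vector of sampling times;
#'   defaults to the model's `default_times`.
#' @param rtol,atol relative/absolute solver tolerances.  The defaults
#'   (`1e-8`, `1e-10`) are tight enough that fitness differences between
#'   nearby parameter vectors exceed solver noise.
#' @param maxsteps maximal internal solver steps per output interval; the
#'   built-in models need well under 100, so the default mainly bounds the
#'   cost of abandoning pathological candidate vectors during global search.
#' @param initial_state optional replacement initial state.
#' @param full if `TRUE`, return all states rather than only observed ones.
#' @return a `trajectory`: list with `times` and an `N x K` matrix `states`
#'   (columns named after the observed species).
#' @export
integrate_model <- function(model, params, times = NULL,
                            rtol = 1e-8, atol = 1e-10, maxsteps = 1000,
                            initial_state = NULL, full = FALSE) {
  stopifnot(inherits(model, "ode_model"))
  if (is.null(times)) times <- model$default_times
  if (is.null(times)) stop("no sampling times given")
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  params <- as.numeric(params)
  if (length(params) != length(model$param_names))
    stop("expected ", length(model$param_names), " parameters, got ",
         length(params))
  if (any(!is.finite(params))) .integration_failure(params, "non-finite parameters")
  y0 <- if (is.null(initial_state)) model$initial_state else {
    stopifnot(length(initial_state) == length(model$state_names))
    stats::setNames(as.numeric(initial_state), model$state_names)
  }

  out <- if (!is.null(model$compiled)) {
    .quiet_try(deSolve::ode(
      y = y0, times = times, func = model$compiled$func, parms = params,
      dllname = model$compiled$dllname, initfunc = model$compiled$initfunc,
      method = "lsoda", rtol = rtol, atol = atol, maxsteps = maxsteps))
  } else {
    derivs <- function(t, y, p) {
      list(as.numeric(model$rhs(y, p, t, model$input)))
    }
    .quiet_try(deSolve::ode(
      y = y0, times = times, func = derivs, parms = params,
      method = "lsoda", rtol = rtol, atol = atol, maxsteps = maxsteps))
  }

  if (inherits(out, "try-error")) .integration_failure(params, "solver error")
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) .integration_failure(params, "solver did not converge")
  if (nrow(out) != length(times) || any(!is.finite(out)))
    .integration_failure(params, "non-finite trajectory")

  states <- out[, -1L, drop = FALSE]
  obs <- if (full) states else states[, model$observed, drop = FALSE]
  if (any(obs < -10 * atol))
    warning("observed state went below -10*atol; concentrations cannot be negative",
            call. = FALSE)
  structure(list(times = times, states = obs), class = "trajectory")
}

# evaluate a solver call with its console chatter silenced: failed
# integrations on hopeless parameter vectors are routine during global
# search and their step-size diagnostics would flood the output
.quiet_try <- function(expr) {
  sink(nullfile())
  on.exit(sink())
  try(suppressWarnings(expr), silent = TRUE)
}

.integration_failure <- function(params, msg) {
  stop(structure(class = c("fireflyde_integration_failure", "error", "condition"),
                 list(message = paste0("integration failure: ", msg),
                      call = sys.call(-1), params = params)))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points, ",
      ncol(x$states), " species (", paste(colnames(x$states), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
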