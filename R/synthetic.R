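#' Per-species noise scale for a trajectory
#'
#' The measurement-noise model is homoscedastic within a species: the noise
#' standard deviation for species `k` is `level` times the root-mean-square
#' of that species' noiseless trajectory, constant over time.  A 25% noise
#' level therefore yields a single per-species noise variance, which is what
#' the identifiability test compares residual variances against.
#'
#' @param trajectory a `trajectory` from [integrate_model()] (or any list
#'   with an `N x K` `states` matrix).
#' @param level non-negative noise fraction (0.25 = 25% noise).
#' @return named numeric vector of per-species standard deviations.
#' @export
noise_scale <- function(trajectory, level) {
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0)
  states <- trajectory$states
  if (is.null(states) || length(states) == 0L || nrow(states) == 0L)
    stop("empty trajectory")
  level * sqrt(colMeans(states^2))
}

#' Generate an in-silico noisy dataset
#'
#' Simulates the model at the given parameters, then superimposes
#' uncorrelated Gaussian noise, independently per time point and species,
#' with per-species standard deviation from [noise_scale()].  Negative noisy
#' concentrations are not truncated (recorded in the dataset metadata).  The
#' dataset records the generating parameters, the theoretical noise sd, the
#' realized noise variance `mean(eps^2)` per species, and the seed, so
#' recovery and identifiability tests can compare against the truth.
#'
#' @param model an [ode_model()].
#' @param params generating ("true") parameter vector; defaults to the
#'   model's `default_params`.
#' @param times sampling grid; defaults to the model's `default_times`.
#' @param level noise fraction (default 0.25, i.e. 25% white Gaussian noise).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#'   The caller's RNG state is preserved.
#' @param initial_state optional replacement initial state.
#' @return a `ts_dataset`: list with `times`, `observations` (`N x K`),
#'   `species`, `noise_sd`, `noise_level`, `realized_noise_var`, `source`
#'   (model name + true params + initial state), and `seed`.
#' @export
generate_dataset <- function(model, params = NULL, times = NULL, level = 0.25,
                             seed = NULL, initial_state = NULL) {
  stopifnot(inherits(model, "ode_model"))
  if (is.null(params)) params <- model$default_params
  if (is.null(params)) stop("no parameters given and model has no defaults")
  traj <- integrate_model(model, params, times, initial_state = initial_state)
  n <- length(traj$times)
  if (n < 2L) stop("need at least 2 time points")
  sds <- noise_scale(traj, level)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(as.integer(seed))
  }
  eps <- matrix(stats::rnorm(n * length(sds)), nrow = n) %*% diag(sds, length(sds))
  y <- traj$states + eps
  colnames(y) <- colnames(traj$states)

  structure(
    list(times = traj$times,
         observations = y,
         species = colnames(traj$states),
         noise_sd = sds,
         noise_level = level,
         realized_noise_var = stats::setNames(colMeans(eps^2), names(sds)),
         truncated_negative = FALSE,
         source = list(model = model$name,
                       params = stats::setNames(as.numeric(params), model$param_names),
                       initial_state = if (is.null(initial_state))
                         model$initial_state else initial_state),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "ts_dataset")
}

#' Construct a time-series dataset by hand
#'
#' Lower-level constructor used by [read_dataset()] and tests; validates the
#' dataset invariants (at least two samples, finite observations, matching
#' dimensions).
#'
#' @param times strictly increasing numeric vector.
#' @param observations `N x K` numeric matrix, columns named by species.
#' @param noise_sd optional per-species noise sd.
#' @param source,seed,realized_noise_var optional provenance metadata.
#' @param noise_level optional scalar noise fraction.
#' @return a `ts_dataset`.
#' @export
ts_dataset <- function(times, observations, noise_sd = NULL, noise_level = NA,
                       realized_noise_var = NULL, source = NULL, seed = NA) {
  times <- as.numeric(times)
  observations <- as.matrix(observations)
  if (length(times) < 2L) stop("need at least 2 time points")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (nrow(observations) != length(times))
    stop("observations must have one row per time point")
  if (any(!is.finite(observations))) stop("observations must be finite")
  if (!is.null(noise_sd) && any(noise_sd < 0)) stop("noise_sd must be >= 0")
  structure(
    list(times = times, observations = observations,
         species = colnames(observations), noise_sd = noise_sd,
         noise_level = noise_level, realized_noise_var = realized_noise_var,
         truncated_negative = FALSE, source = source,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat("<ts_dataset> ", length(x$times), " time points x ",
      ncol(x$observations), " species (",
      paste(x$species, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$source$model))
    cat("  source: ", x$source$model, ", noise level ",
        x$noise_level, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
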