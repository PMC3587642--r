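#' Residuals of a fitted model against a dataset
#'
#' `res[n, k] = y[n, k] - yhat[n, k]`, the estimated measurement noise under
#' the fitted parameters, with the prediction integrated at the dataset's
#' sampling times.  Integration failure is an error here: the
#' identifiability test is only meaningful for a successfully simulated fit.
#'
#' @param params fitted parameter vector.
#' @param model an [ode_model()].
#' @param data a `ts_dataset`.
#' @return `N x K` residual matrix, columns named by species.
#' @export
compute_residuals <- function(params, model, data) {
  stopifnot(inherits(model, "ode_model"), inherits(data, "ts_dataset"))
  init <- data$source$initial_state
  pred <- integrate_model(model, params, data$times, initial_state = init)
  obs_names <- colnames(pred$states)
  if (!identical(colnames(data$observations), obs_names))
    stop("dataset species do not match model observed species")
  data$observations - pred$states
}

#' Residual variance point
#'
#' `xi = (1/N) * sum(res^2)` per species: the mean squared residual, the
#' point estimate of the measurement-noise variance under the fitted
#' parameters.  An optional degrees-of-freedom correction subtracts
#' `correction` (e.g. the number of estimated parameters) from the
#' denominator; it is off by default.
#'
#' @param residuals numeric vector (one species) or `N x K` matrix.
#' @param correction non-negative integer subtracted from `N` in the
#'   denominator (default 0).
#' @return scalar, or named per-species vector for matrix input.
#' @export
variance_point <- function(residuals, correction = 0L) {
  if (is.matrix(residuals)) {
    if (nrow(residuals) < 2L) stop("need at least 2 residuals")
    return(colSums(residuals^2) / (nrow(residuals) - correction))
  }
  if (length(residuals) < 2L) stop("need at least 2 residuals")
  sum(residuals^2) / (length(residuals) - correction)
}

#' Chi-square confidence interval for a noise variance
#'
#' Equal-tails chi-square interval for a Gaussian variance estimated from
#' `N` residuals: with `delta = 1 - gamma`,
#' `[N * xi / chi2(1 - delta/2, N), N * xi / chi2(delta/2, N)]`, where
#' `chi2(p, N)` is the `p`-quantile of the chi-square distribution with `N`
#' degrees of freedom.  The interval always contains `xi` and its width
#' shrinks to zero as `N` grows.
#'
#' @param xi non-negative variance point.
#' @param N number of samples (>= 2).
#' @param gamma confidence level in `(0, 1)`; the study default is 0.95.
#' @return numeric `c(lower, upper)`, with the chi-square quantiles used
#'   attached as attribute `"chi2_quantiles"`.
#' @export
variance_interval <- function(xi, N, gamma = 0.95) {
  if (N < 2L) stop("N must be >= 2")
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0, 1)")
  if (xi < 0) stop("xi must be >= 0")
  delta <- 1 - gamma
  q_hi <- stats::qchisq(1 - delta / 2, df = N)
  q_lo <- stats::qchisq(delta / 2, df = N)
  structure(c(lower = N * xi / q_hi, upper = N * xi / q_lo),
            chi2_quantiles = c(q_lo, q_hi))
}

#' Chi-square identifiability verdict for one species
#'
#' Passes when the known (real) noise variance lies inside the chi-square
#' interval around the residual variance point, endpoints inclusive.  A
#' variance point well below the real variance (interval entirely under it)
#' is the signature of overfitting noise; one well above it indicates model
#' mismatch.
#'
#' @param xi variance point (unused in the comparison, kept for reporting).
#' @param interval numeric `c(lower, upper)` from [variance_interval()].
#' @param sigma2_real known noise variance.
#' @return logical pass/fail.
#' @export
chi2_identifiability_test <- function(xi, interval, sigma2_real) {
  sigma2_real >= interval[[1]] && sigma2_real <= interval[[2]]
}

#' Practical-identifiability report for a fitted model
#'
#' Runs the full a-posteriori test: residuals of the fit, per-species
#' variance points, chi-square variance intervals at confidence `gamma`, and
#' a per-species pass/fail against the real noise variance.  The model-level
#' verdict passes only if every observed species passes.  For synthetic
#' datasets the real variance defaults to the realized noise variance
#' recorded at generation time.
#'
#' @param params fitted parameter vector.
#' @param model an [ode_model()].
#' @param data a `ts_dataset`.
#' @param gamma confidence level (default 0.95).
#' @param sigma2_real per-species known noise variances; defaults to
#'   `data$realized_noise_var`.
#' @return a `variance_report`: list with a per-species `table`
#'   (real variance, variance point, interval, verdict), `gamma`, `N`,
#'   `passed` (model-level conjunction).
#' @export
identify_model <- function(params, model, data, gamma = 0.95,
                           sigma2_real = NULL) {
  res <- compute_residuals(params, model, data)
  if (is.null(sigma2_real)) sigma2_real <- data$realized_noise_var
  if (is.null(sigma2_real))
    stop("real noise variance unknown; supply sigma2_real")
  N <- nrow(res)
  xi <- variance_point(res)
  tab <- do.call(rbind, lapply(seq_along(xi), function(k) {
    ci <- variance_interval(xi[[k]], N, gamma)
    data.frame(species = colnames(res)[k],
               real_variance = sigma2_real[[k]],
               variance_point = xi[[k]],
               lower = ci[[1]], upper = ci[[2]],
               passed = chi2_identifiability_test(xi[[k]], ci, sigma2_real[[k]]))
  }))
  structure(list(table = tab, gamma = gamma, N = N,
                 passed = all(tab$passed), model = model$name,
                 params = params),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat("Chi-square identifiability test  (model ", x$model,
      ", gamma = ", x$gamma, ", N = ", x$N, ")\n", sep = "")
  tab <- x$table
  fmt <- function(v) formatC(v, format = "e", digits = 2)
  out <- data.frame(
    Species = tab$species,
    `Real Variance` = fmt(tab$real_variance),
    `Variance Point` = fmt(tab$variance_point),
    Interval = paste0("[", fmt(tab$lower), ", ", fmt(tab$upper), "]"),
    check.names = FALSE)
  print(out, row.names = FALSE)
  cat("Chi-square test:", if (x$passed) "Pass" else "Fail", "\n")
  invisible(x)
}

#' Serialize a variance report to JSON
#'
#' @param report a `variance_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(model = report$model, gamma = report$gamma, N = report$N,
         passed = report$passed, species = report$table),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
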