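#' Gaussian-noise Akaike information criterion
#'
#' `AIC = N * log(RS / N) + 2 * M` for a model with `M` parameters whose
#' residual sum of squares over `N` samples is `RS`, under independent
#' normally distributed measurement noise.  Smaller is better.  A ranking by
#' this form is invariant to a common rescaling of the data when both
#' candidates' `RS` scale identically (the `N*log` terms shift equally).
#'
#' @param RS residual sum of squares (> 0; a perfect fit has no finite AIC
#'   and must be reported separately).
#' @param N number of samples.
#' @param M number of model parameters.
#' @return the AIC value.
#' @export
compute_aic <- function(RS, N, M) {
  if (RS <= 0) stop("RS must be > 0 (perfect fits have no finite AIC)")
  if (N < 1) stop("N must be >= 1")
  if (M < 0) stop("M must be >= 0")
  N * log(RS / N) + 2 * M
}

#' Rank candidate models on one dataset
#'
#' For each candidate (a model plus its fitted parameters, all fitted on the
#' same dataset) this computes per-species residual sums of squares,
#' per-species AIC (with `M` = the candidate's full parameter count), and the
#' chi-square identifiability report.  Among candidates that pass the
#' chi-square test, the one with the smallest total AIC (summed over
#' species) is selected; if none passes, no adequate model is reported.
#'
#' @param candidates named list; each element a list with components `model`
#'   (an [ode_model()]) and `params` (its fitted vector).  Unnamed elements
#'   are named after their model.
#' @param data a `ts_dataset` shared by all candidates.
#' @param gamma chi-square confidence level.
#' @param sigma2_real optional known noise variances (defaults to the
#'   dataset's realized noise variance).
#' @return a `model_selection`: list with per-candidate `scores` (each
#'   holding `RS`, `AIC`, `report`, `total_aic`, `passed`), a summary
#'   `table`, and `selected` (candidate name, or `NA` if none passes).
#' @export
compare_models <- function(candidates, data, gamma = 0.95,
                           sigma2_real = NULL) {
  stopifnot(inherits(data, "ts_dataset"))
  if (length(candidates) < 2L)
    message("model selection with fewer than 2 candidates is trivial")
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    names(candidates) <- vapply(candidates, function(c) c$model$name, "")

  N <- length(data$times)
  scores <- lapply(candidates, function(cand) {
    stopifnot(inherits(cand$model, "ode_model"))
    res <- compute_residuals(cand$params, cand$model, data)
    RS <- colSums(res^2)
    M <- length(cand$model$param_names)
    aic <- vapply(RS, compute_aic, 0, N = N, M = M)
    report <- identify_model(cand$params, cand$model, data, gamma = gamma,
                             sigma2_real = sigma2_real)
    list(model = cand$model$name, RS = RS, AIC = aic,
         total_aic = sum(aic), report = report, passed = report$passed)
  })

  passed <- vapply(scores, `[[`, TRUE, "passed")
  total_aic <- vapply(scores, `[[`, 0, "total_aic")
  selected <- if (any(passed)) {
    names(scores)[passed][which.min(total_aic[passed])]
  } else NA_character_

  tab <- do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    data.frame(candidate = nm, species = names(s$AIC),
               variance_point = s$report$table$variance_point,
               lower = s$report$table$lower, upper = s$report$table$upper,
               AIC = unname(s$AIC), passed = s$report$table$passed)
  }))

  structure(list(scores = scores, table = tab, selected = selected,
                 gamma = gamma, N = N),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection over", length(x$scores), "candidates (gamma =",
      x$gamma, ")\n")
  fmt <- function(v) formatC(v, format = "e", digits = 2)
  for (nm in names(x$scores)) {
    s <- x$scores[[nm]]
    t <- s$report$table
    cat("  ", nm, ": ", if (s$passed) "Pass" else "Fail",
        "  total AIC = ", fmt(s$total_aic), "\n", sep = "")
    for (k in seq_len(nrow(t)))
      cat("     ", t$species[k], ": point ", fmt(t$variance_point[k]),
          "  interval [", fmt(t$lower[k]), ", ", fmt(t$upper[k]),
          "]  AIC ", fmt(s$AIC[k]), "\n", sep = "")
  }
  if (is.na(x$selected)) cat("No adequate model (no candidate passed).\n")
  else cat("Selected:", x$selected, "\n")
  invisible(x)
}

#' Serialize a model-selection report to JSON
#'
#' @param selection a `model_selection`.
#' @param path output path.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(gamma = selection$gamma, N = selection$N,
         selected = selection$selected, table = selection$table),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
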