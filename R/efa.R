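#' Optimizer configuration
#'
#' Hyperparameters of the hybrid Firefly/Differential-Evolution optimizer and
#' of the plain-Firefly baseline.  Randomness is driven by a single seeded
#' generator per run; all uniform draws (initialization, movement noise, weak
#' re-seeding, mutation scaling, crossover) come from it in a fixed order, so
#' runs are exactly replayable.
#'
#' @param bounds numeric `M x 2` matrix of `[lower, upper]` search bounds.
#' @param NP population size (>= 4).
#' @param max_iter iteration budget.
#' @param beta0 initial attractiveness of the Firefly move.
#' @param phi light-absorption coefficient; attraction decays as
#'   `beta0 * exp(-phi * r^2)` with Euclidean distance `r`.
#' @param alpha randomization weight of the Firefly move noise term.
#' @param MR mutation rate scaling the DE difference vector, in `[0, 1]`.
#' @param CR crossover rate of the binomial DE crossover, in `[0, 1]`.
#' @param potential_fraction share of the population classed "potential"
#'   (fittest members) at each iteration, in `(0, 1)`.
#' @param weak_width width, as a fraction of the search box, of the region
#'   around the incumbent best in which weak members are re-seeded.
#' @param fitness_threshold optional early-stop fitness ("acceptable fitness
#'   value"); disabled by default.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param eval_mode `"per_move"` re-evaluates a firefly's fitness after each
#'   accepted pairwise move (default); `"per_sweep"` once per full sweep.
#' @return an `efa_config` list.
#' @export
efa_config <- function(bounds, NP = 20, max_iter = 100, beta0 = 1, phi = 1,
                       alpha = 0.2, MR = 0.5, CR = 0.9,
                       potential_fraction = 0.5, weak_width = 0.1,
                       fitness_threshold = NULL, seed = NULL,
                       eval_mode = c("per_move", "per_sweep")) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L) stop("'bounds' must be an M x 2 matrix")
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  if (any(bounds[, 1] > bounds[, 2])) stop("lower bounds must not exceed upper bounds")
  NP <- as.integer(NP)
  if (NP < 4L) stop("NP must be >= 4")
  if (MR < 0 || MR > 1) stop("MR must be in [0, 1]")
  if (CR < 0 || CR > 1) stop("CR must be in [0, 1]")
  if (potential_fraction <= 0 || potential_fraction >= 1)
    stop("potential_fraction must be in (0, 1)")
  if (beta0 < 0 || phi < 0 || alpha < 0)
    stop("beta0, phi and alpha must be >= 0")
  if (weak_width < 0) stop("weak_width must be >= 0")
  structure(
    list(bounds = bounds, NP = NP, max_iter = as.integer(max_iter),
         beta0 = beta0, phi = phi, alpha = alpha, MR = MR, CR = CR,
         potential_fraction = potential_fraction, weak_width = weak_width,
         fitness_threshold = fitness_threshold,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         eval_mode = match.arg(eval_mode)),
    class = "efa_config")
}

.clip <- function(x, bounds) pmin(pmax(x, bounds[, 1]), bounds[, 2])

#' Initialize the firefly population
#'
#' Each component is drawn as `LB + C1 * (UB - LB)` with a fresh uniform(0,1)
#' draw `C1` per component, so every member lies inside the search box, and
#' fitness is evaluated for all members.
#'
#' @param fn objective function of a parameter vector.
#' @param config an [efa_config()].
#' @return a `population`: list with `members` (`NP x M` matrix), `fitness`,
#'   `best_params`, `best_fitness`.
#' @export
init_population <- function(fn, config) {
  b <- config$bounds
  M <- nrow(b)
  members <- matrix(stats::runif(config$NP * M), nrow = config$NP)
  members <- sweep(sweep(members, 2, b[, 2] - b[, 1], `*`), 2, b[, 1], `+`)
  fitness <- apply(members, 1, fn)
  fitness[!is.finite(fitness) | is.na(fitness)] <- Inf
  ib <- which.min(fitness)
  structure(list(members = members, fitness = fitness,
                 best_params = members[ib, ], best_fitness = fitness[ib]),
            class = "population")
}

#' Firefly attraction
#'
#' `beta = beta0 * exp(-phi * r^2)`: attraction decays with the squared
#' Euclidean distance between two solutions, scaled by the light-absorption
#' coefficient.
#'
#' @param r non-negative distance.
#' @param config an [efa_config()].
#' @return attraction value in `[0, beta0]`.
#' @export
attraction <- function(r, config) {
  if (any(r < 0)) stop("distance must be >= 0")
  config$beta0 * exp(-config$phi * r^2)
}

#' Move one firefly toward a fitter neighbour
#'
#' Performed only when the neighbour `x_j` has strictly better fitness:
#' `x_i <- x_i + beta * (x_j - x_i) + alpha * (C2 - 0.5)` with a fresh
#' uniform(0,1) draw `C2` per component, then clipped to the bounds.
#' Otherwise `x_i` is returned unchanged.
#'
#' @param x_i,x_j parameter vectors of the moving and attracting fireflies.
#' @param J_i,J_j their fitness values.
#' @param config an [efa_config()].
#' @return the updated `x_i`.
#' @export
firefly_move <- function(x_i, x_j, J_i, J_j, config) {
  stopifnot(length(x_i) == length(x_j))
  if (!(J_j < J_i)) return(x_i)
  r <- sqrt(sum((x_i - x_j)^2))
  beta <- attraction(r, config)
  x_new <- x_i + beta * (x_j - x_i) +
    config$alpha * (stats::runif(length(x_i)) - 0.5)
  .clip(x_new, config$bounds)
}

#' Partition the population into potential and weak members
#'
#' Members are sorted ascending by fitness (stable: ties keep their original
#' order); the first `ceiling(potential_fraction * NP)` are "potential", the
#' remainder "weak".
#'
#' @param pop a `population` (or a plain fitness vector).
#' @param config an [efa_config()].
#' @return list with integer index vectors `potential` and `weak`.
#' @export
partition_population <- function(pop, config) {
  fitness <- if (inherits(pop, "population")) pop$fitness else as.numeric(pop)
  ord <- order(fitness)               # order() is a stable sort
  n_pot <- ceiling(config$potential_fraction * length(fitness))
  list(potential = ord[seq_len(n_pot)],
       weak = if (n_pot < length(fitness)) ord[(n_pot + 1):length(fitness)]
              else integer(0))
}

#' Re-seed a weak member around the incumbent best
#'
#' Weak members are randomly re-populated to escape suboptimal regions:
#' per component, `x_d <- x_min_d + (C3 - 0.5) * w * (UB_d - LB_d)` with a
#' fresh uniform(0,1) draw `C3` and re-seeding width `w = weak_width`,
#' clipped to the bounds.
#'
#' @param x_i the weak member (used only for its length).
#' @param x_min the current best solution vector.
#' @param config an [efa_config()].
#' @return the re-seeded vector.
#' @export
weak_update <- function(x_i, x_min, config) {
  stopifnot(length(x_i) == length(x_min))
  b <- config$bounds
  x_new <- x_min + (stats::runif(length(x_i)) - 0.5) *
    config$weak_width * (b[, 2] - b[, 1])
  .clip(x_new, config$bounds)
}

#' DE mutation on the potential set
#'
#' `v_i = x_i + C4 * MR * (x_r1 - x_r2)` with donors `r1 != r2 != i` drawn
#' uniformly from the potential set and a fresh uniform(0,1) scalar `C4`;
#' clipped to the bounds.
#'
#' @param potential matrix of potential members (rows).
#' @param i row index of the base member within `potential`.
#' @param config an [efa_config()].
#' @return the mutated vector `v_i`.
#' @export
de_mutate <- function(potential, i, config) {
  potential <- as.matrix(potential)
  n <- nrow(potential)
  if (n < 3L)
    stop("potential set too small for mutation (need >= 3 members)")
  donors <- sample(setdiff(seq_len(n), i), 2L)
  C4 <- stats::runif(1)
  v <- potential[i, ] + C4 * config$MR * (potential[donors[1], ] - potential[donors[2], ])
  .clip(v, config$bounds)
}

#' DE binomial crossover
#'
#' Per component, the offspring takes the mutated value when a fresh
#' uniform(0,1) draw is `<= CR` or the component is the single forced index
#' `j_rand` (chosen uniformly), and the parent value otherwise.  The forced
#' index guarantees the offspring differs from the parent whenever the
#' mutated vector does.
#'
#' @param x_i parent vector.
#' @param v_i mutated vector.
#' @param config an [efa_config()].
#' @return the offspring vector.
#' @export
de_crossover <- function(x_i, v_i, config) {
  stopifnot(length(x_i) == length(v_i))
  M <- length(x_i)
  j_rand <- sample.int(M, 1L)
  take <- stats::runif(M) <= config$CR
  take[j_rand] <- TRUE
  ifelse(take, v_i, x_i)
}

#' DE greedy selection
#'
#' Evaluates the offspring and keeps it only on strict improvement; ties and
#' failed integrations (infinite fitness) keep the parent, so the population
#' size is unchanged and the best fitness never worsens.
#'
#' @param x_i parent vector with fitness `J_i`.
#' @param x_off offspring vector.
#' @param fn objective function.
#' @param J_i parent fitness (evaluated if missing).
#' @return list `(x, fitness, accepted)`.
#' @export
de_select <- function(x_i, x_off, fn, J_i = NULL) {
  if (is.null(J_i)) J_i <- fn(x_i)
  J_off <- fn(x_off)
  if (!is.finite(J_off) || is.na(J_off)) J_off <- Inf
  if (J_off < J_i) list(x = x_off, fitness = J_off, accepted = TRUE)
  else list(x = x_i, fitness = J_i, accepted = FALSE)
}

# ---------------------------------------------------------------------------
# engines

#' Optimize an arbitrary objective with the hybrid or plain algorithm
#'
#' Core engine operating on a bare objective function; [run_efa()] and
#' [run_fa()] wrap it with the least-squares fitness of a model/dataset
#' pair.  One iteration of the hybrid algorithm performs (i) a full pairwise
#' firefly sweep in which each member attempts a move toward every fitter
#' member, (ii) a stable-sort partition into potential and weak members,
#' (iii) DE mutation/crossover/greedy selection on the potential members, and
#' (iv) re-seeding of the weak members around the incumbent best.  The plain
#' algorithm performs step (i) only.  The incumbent best is archived
#' separately, so the reported best-fitness trace is non-increasing even
#' though individual members may move to worse positions.
#'
#' @param fn objective function of a parameter vector; smaller is better.
#' @param config an [efa_config()].
#' @param algorithm `"efa"` (hybrid) or `"fa"` (plain firefly baseline).
#' @return a `fit_result`: list with `best_params`, `best_fitness`, `trace`
#'   (per-iteration incumbent fitness), `evaluations`, `iterations`, `seed`,
#'   `algorithm` and the `config`.
#' @export
efa_optimize <- function(fn, config, algorithm = c("efa", "fa")) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(config, "efa_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_evals <- 0L
  fneval <- function(x) {
    n_evals <<- n_evals + 1L
    v <- fn(x)
    if (!is.finite(v) || is.na(v)) Inf else v
  }

  pop <- init_population(fneval, config)
  members <- pop$members
  fitness <- pop$fitness
  best_x <- pop$best_params
  best_J <- pop$best_fitness
  NP <- config$NP
  per_move <- config$eval_mode == "per_move"

  trace <- numeric(0)
  iter_done <- 0L
  for (iter in seq_len(config$max_iter)) {
    # firefly sweep: each member attempts a move toward every fitter member
    for (i in seq_len(NP)) {
      moved <- FALSE
      for (j in seq_len(NP)) {
        if (fitness[j] < fitness[i]) {
          members[i, ] <- firefly_move(members[i, ], members[j, ],
                                       fitness[i], fitness[j], config)
          moved <- TRUE
          if (per_move) {
            fitness[i] <- fneval(members[i, ])
            if (fitness[i] < best_J) { best_J <- fitness[i]; best_x <- members[i, ] }
          }
        }
      }
      if (!per_move && moved) {
        fitness[i] <- fneval(members[i, ])
        if (fitness[i] < best_J) { best_J <- fitness[i]; best_x <- members[i, ] }
      }
    }

    if (algorithm == "efa") {
      part <- partition_population(fitness, config)
      pot <- part$potential
      # DE refinement of the potential members (needs >= 3 of them)
      if (length(pot) >= 3L) {
        pot_members <- members[pot, , drop = FALSE]
        for (p in seq_along(pot)) {
          i <- pot[p]
          v <- de_mutate(pot_members, p, config)
          off <- de_crossover(members[i, ], v, config)
          sel <- de_select(members[i, ], off, fneval, J_i = fitness[i])
          members[i, ] <- sel$x
          fitness[i] <- sel$fitness
          if (fitness[i] < best_J) { best_J <- fitness[i]; best_x <- members[i, ] }
        }
      }
      # weak members are re-seeded around the incumbent best
      for (i in part$weak) {
        members[i, ] <- weak_update(members[i, ], best_x, config)
        fitness[i] <- fneval(members[i, ])
        if (fitness[i] < best_J) { best_J <- fitness[i]; best_x <- members[i, ] }
      }
    }

    trace <- c(trace, best_J)
    iter_done <- iter
    if (!is.null(config$fitness_threshold) && best_J <= config$fitness_threshold)
      break
  }

  structure(
    list(best_params = best_x, best_fitness = best_J, trace = trace,
         evaluations = n_evals, iterations = iter_done,
         seed = config$seed, algorithm = algorithm, config = config),
    class = "fit_result")
}

#' Fit model parameters to a dataset
#'
#' `run_efa()` runs the hybrid Firefly/DE optimizer on the least-squares
#' fitness of `model` against `data`; `run_fa()` runs the plain-Firefly
#' baseline (no partition, no DE step, no weak re-seeding) at the same
#' budget.  A subset of parameters can be estimated while the rest are
#' clamped (e.g. single-parameter recovery studies).
#'
#' @param model an [ode_model()].
#' @param data a `ts_dataset`.
#' @param config an [efa_config()]; its bounds must match the number of free
#'   parameters.  If omitted, a default configuration over the model bounds
#'   is used.
#' @param free character vector of parameter names to estimate (`NULL` = all).
#' @param fixed_params clamped values for the non-free parameters (defaults
#'   to the model's `default_params`).
#' @param ... passed to [efa_config()] when `config` is omitted.
#' @return a `fit_result` whose `best_params` are named after the free
#'   parameters.
#' @export
run_efa <- function(model, data, config = NULL, free = NULL,
                    fixed_params = NULL, ...) {
  .run_fit(model, data, config, free, fixed_params, algorithm = "efa", ...)
}

#' @rdname run_efa
#' @export
run_fa <- function(model, data, config = NULL, free = NULL,
                   fixed_params = NULL, ...) {
  .run_fit(model, data, config, free, fixed_params, algorithm = "fa", ...)
}

.run_fit <- function(model, data, config, free, fixed_params, algorithm, ...) {
  fn <- make_objective(model, data, free = free, fixed_params = fixed_params)
  idx <- attr(fn, "free_idx")
  if (is.null(config)) config <- efa_config(bounds = model$bounds[idx, , drop = FALSE], ...)
  if (nrow(config$bounds) != length(idx))
    stop("config bounds rows (", nrow(config$bounds),
         ") must match number of free parameters (", length(idx), ")")
  res <- efa_optimize(fn, config, algorithm = algorithm)
  names(res$best_params) <- attr(fn, "free_names")
  res$model <- model$name
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$algorithm, if (!is.null(x$model)) paste0(" on ", x$model),
      "\n  best fitness: ", format(x$best_fitness, digits = 6),
      " after ", x$iterations, " iterations (",
      x$evaluations, " evaluations)\n", sep = "")
  if (!is.null(names(x$best_params)))
    cat("  best params : ",
        paste(names(x$best_params), signif(x$best_params, 5),
              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a fitness trace as CSV
#'
#' @param fit a `fit_result`.
#' @param path output CSV path (columns `iteration`, `best_fitness`).
#' @param every write every `every`-th iteration (the last is always kept).
#' @export
write_trace <- function(fit, path, every = 1L) {
  keep <- unique(c(seq(1L, length(fit$trace), by = every), length(fit$trace)))
  utils::write.csv(data.frame(iteration = keep, best_fitness = fit$trace[keep]),
                   path, row.names = FALSE)
  invisible(path)
}
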