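test_that("initialization fills the search box by the affine-uniform law", {
  # degenerate interval collapses every member onto it
  cfg <- efa_config(bounds = cbind(rep(3, 2), rep(3, 2)), NP = 6, seed = 1)
  pop <- init_population(sphere, cfg)
  expect_true(all(pop$members == 3))

  # members lie in bounds for any seed
  for (s in 1:5) {
    cfg <- efa_config(bounds = cbind(c(-2, 0), c(1, 5)), NP = 10, seed = s)
    pop <- init_population(sphere, cfg)
    expect_true(all(pop$members >= rep(c(-2, 0), each = 10)))
    expect_true(all(pop$members <= rep(c(1, 5), each = 10)))
    expect_equal(pop$best_fitness, min(pop$fitness))
  }

  # Monte-Carlo mean against the uniform law: (LB+UB)/2 within 3 SE
  cfg <- efa_config(bounds = cbind(2, 8), NP = 10000, seed = 12)
  pop <- init_population(function(x) 0, cfg)
  se <- (8 - 2) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(pop$members) - 5), 3 * se)
})

test_that("attraction follows beta0 * exp(-phi * r^2)", {
  cfg <- efa_config(bounds = cbind(0, 1), beta0 = 0.8, phi = 2)
  expect_equal(attraction(0, cfg), 0.8)
  cfg0 <- efa_config(bounds = cbind(0, 1), beta0 = 0.8, phi = 0)
  expect_equal(attraction(c(0, 1, 10), cfg0), rep(0.8, 3))
  cfg1 <- efa_config(bounds = cbind(0, 1), beta0 = 1, phi = 1)
  expect_equal(attraction(1, cfg1), exp(-1))
  expect_equal(attraction(1, cfg1), 0.367879, tolerance = 1e-5)
  r <- seq(0, 3, by = 0.1)
  expect_true(all(diff(attraction(r, cfg)) <= 0))
  expect_error(attraction(-1, cfg), ">= 0")
})

test_that("firefly moves only toward strictly fitter neighbours", {
  cfg <- efa_config(bounds = cbind(rep(-10, 2), rep(10, 2)),
                    beta0 = 0.5, phi = 0, alpha = 0, seed = 1)
  x_i <- c(0, 0); x_j <- c(2, 4)
  # no move toward an equal or worse neighbour
  expect_equal(firefly_move(x_i, x_j, J_i = 1, J_j = 1, cfg), x_i)
  expect_equal(firefly_move(x_i, x_j, J_i = 1, J_j = 2, cfg), x_i)
  # hand evaluation: beta = 0.5, no noise -> midpoint
  expect_equal(firefly_move(x_i, x_j, J_i = 2, J_j = 1, cfg), c(1, 2))
  # full attraction, no absorption, no noise lands on x_j
  cfg_full <- efa_config(bounds = cbind(rep(-10, 2), rep(10, 2)),
                         beta0 = 1, phi = 0, alpha = 0)
  expect_equal(firefly_move(x_i, x_j, 2, 1, cfg_full), x_j)
  # noise respects the bounds through clipping
  cfg_noisy <- efa_config(bounds = cbind(rep(0, 2), rep(2, 2)), alpha = 50)
  for (i in 1:20) {
    out <- firefly_move(c(0, 0), c(2, 2), 2, 1, cfg_noisy)
    expect_true(all(out >= 0 & out <= 2))
  }
})

test_that("partition splits the sorted population with stable ties", {
  cfg <- efa_config(bounds = cbind(0, 1), NP = 4, potential_fraction = 0.5)
  part <- partition_population(c(3, 1, 2, 4), cfg)
  expect_equal(sort(part$potential), c(2, 3))   # fitness {1, 2}
  expect_equal(sort(part$weak), c(1, 4))

  part_tie <- partition_population(rep(7, 4), cfg)
  expect_equal(part_tie$potential, c(1, 2))     # stable tie-break

  for (s in 1:10) {
    set.seed(s)
    fit <- runif(9)
    cfg9 <- efa_config(bounds = cbind(0, 1), NP = 9, potential_fraction = 0.4)
    p <- partition_population(fit, cfg9)
    expect_equal(length(p$potential), ceiling(0.4 * 9))
    expect_equal(sort(c(p$potential, p$weak)), 1:9)
  }
})

test_that("weak members re-seed symmetrically around the incumbent best", {
  cfg0 <- efa_config(bounds = cbind(rep(-10, 3), rep(10, 3)), weak_width = 0)
  x_min <- c(1, -2, 3)
  expect_equal(weak_update(c(9, 9, 9), x_min, cfg0), x_min)

  cfg <- efa_config(bounds = cbind(rep(-10, 3), rep(10, 3)), weak_width = 0.4, seed = 5)
  set.seed(5)
  draws <- t(replicate(4000, weak_update(c(0, 0, 0), x_min, cfg)))
  expect_true(all(draws >= -10 & draws <= 10))
  # mean reverts to x_min within Monte-Carlo error (3 SE of the uniform law)
  se <- 0.4 * 20 / sqrt(12) / sqrt(4000)
  expect_true(all(abs(colMeans(draws) - x_min) < 3 * se))
})

test_that("DE mutation scales a donor difference vector by at most MR", {
  cfg <- efa_config(bounds = cbind(rep(-100, 2), rep(100, 2)), MR = 0.6, seed = 2)
  # identical donors (or MR = 0) leave the base vector unchanged
  pot_equal <- rbind(c(1, 1), c(4, 4), c(4, 4))
  expect_equal(de_mutate(pot_equal, 1, cfg), c(1, 1))
  cfg_mr0 <- efa_config(bounds = cbind(rep(-100, 2), rep(100, 2)), MR = 0)
  pot <- rbind(c(1, 1), c(3, 5), c(-2, 7))
  expect_equal(de_mutate(pot, 1, cfg_mr0), c(1, 1))

  # v - x_i is parallel to the donor difference with scale in [0, MR]
  set.seed(7)
  diffvec <- pot[2, ] - pot[3, ]
  for (i in 1:20) {
    v <- de_mutate(pot, 1, cfg)
    step <- v - pot[1, ]
    scale <- step[1] / diffvec[1]
    expect_equal(step, scale * diffvec, tolerance = 1e-12)
    expect_lte(abs(scale), cfg$MR)
  }
  expect_error(de_mutate(pot[1:2, ], 1, cfg), "too small")
})

test_that("binomial crossover mixes parent and mutant componentwise", {
  x <- c(1, 2, 3, 4); v <- c(10, 20, 30, 40)
  cfg1 <- efa_config(bounds = cbind(rep(0, 4), rep(100, 4)), CR = 1)
  expect_equal(de_crossover(x, v, cfg1), v)

  cfg0 <- efa_config(bounds = cbind(rep(0, 4), rep(100, 4)), CR = 0)
  set.seed(3)
  for (i in 1:10) {
    off <- de_crossover(x, v, cfg0)
    expect_equal(sum(off != x), 1)          # exactly the forced index
    expect_true(off[off != x] %in% v)
  }

  cfg <- efa_config(bounds = cbind(rep(0, 4), rep(100, 4)), CR = 0.5)
  for (i in 1:10) {
    off <- de_crossover(x, v, cfg)
    expect_true(all(off == x | off == v))   # selection-from-pair property
  }
})

test_that("greedy selection keeps the parent on ties and failures", {
  fn <- function(x) if (any(x > 5)) Inf else sum(x^2)
  sel <- de_select(c(1, 1), c(10, 10), fn)
  expect_false(sel$accepted)
  expect_equal(sel$x, c(1, 1))

  sel <- de_select(c(2, 2), c(1, 1), fn)
  expect_true(sel$accepted)
  expect_equal(sel$x, c(1, 1))

  sel <- de_select(c(1, 1), c(-1, -1), fn)  # equal fitness: parent kept
  expect_false(sel$accepted)
  expect_equal(sel$x, c(1, 1))
})

test_that("the hybrid optimizer solves the sphere and obeys its contracts", {
  cfg <- sphere_config(M = 2, NP = 20, max_iter = 100, seed = 11)
  res <- efa_optimize(sphere, cfg)
  expect_lt(res$best_fitness, 1e-4)
  expect_true(all(diff(res$trace) <= 0))
  expect_equal(res$best_fitness, res$trace[length(res$trace)])
  expect_true(all(res$best_params >= -5 & res$best_params <= 5))

  # determinism: same seed and config reproduce the run exactly
  res2 <- efa_optimize(sphere, cfg)
  expect_identical(res$best_params, res2$best_params)
  expect_identical(res$trace, res2$trace)

  # baseline converges too, more slowly on median over paired seeds
  fa_best <- efa_best <- numeric(20)
  for (s in 1:20) {
    cfg_s <- sphere_config(M = 2, NP = 15, max_iter = 40, seed = s)
    efa_best[s] <- efa_optimize(sphere, cfg_s)$best_fitness
    fa_best[s] <- efa_optimize(sphere, cfg_s, algorithm = "fa")$best_fitness
  }
  expect_lt(median(fa_best), 1e-2 * 25)  # plain FA does converge
  expect_lte(median(efa_best), median(fa_best))
})

test_that("the optimizer's evaluation count matches the objective's counter", {
  dm <- decay_model()
  ds <- generate_dataset(dm, times = seq(0, 5, length.out = 6),
                         level = 0.1, seed = 1)
  fn <- make_objective(dm, ds)
  cfg <- efa_config(bounds = dm$bounds, NP = 5, max_iter = 4, seed = 2)
  res <- efa_optimize(fn, cfg)
  expect_equal(res$evaluations, objective_evaluations(fn))
  expect_gt(res$evaluations, cfg$NP)  # init plus iteration work
})

test_that("single-parameter fits recover the generating value on clean data", {
  dm <- decay_model()
  ds <- generate_dataset(dm, level = 0, seed = 1)
  cfg <- efa_config(bounds = cbind(0, 10), NP = 10, max_iter = 30, seed = 4)
  fit <- run_efa(dm, ds, cfg)
  expect_equal(unname(fit$best_params), 0.7, tolerance = 1e-3)
  expect_equal(names(fit$best_params), "k")
})

test_that("configuration invariants are enforced", {
  b <- cbind(0, 1)
  expect_error(efa_config(b, NP = 3), "NP")
  expect_error(efa_config(b, MR = 1.2), "MR")
  expect_error(efa_config(b, CR = -0.1), "CR")
  expect_error(efa_config(b, potential_fraction = 1), "potential_fraction")
  expect_error(efa_config(b, alpha = -1), "alpha")
  expect_error(efa_config(cbind(1, 0)), "lower bounds")
  expect_error(efa_config(cbind(0, Inf)), "finite")
})
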