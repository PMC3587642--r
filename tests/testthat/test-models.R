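test_that("p53 right-hand side has the expected reaction structure", {
  state <- c(A = 0.4, B = 0.7, C = 0.2, D = 0.3)
  zero <- rep(0, 9)

  # no reactions, no flux
  expect_equal(unname(p53_rhs(state, zero)), rep(0, 4))

  # constant production is the only nonzero term when k1 alone is active
  k <- zero; k[1] <- 1.7
  expect_equal(unname(p53_rhs(state, k)), c(1.7, 0, 0, 0))

  # complex-formation flux k3*A*B enters dA and dB with -, dC with +
  k3on <- zero; k3on[3] <- 1.3
  flux <- p53_rhs(state, k3on) - p53_rhs(state, zero)
  expect_equal(unname(flux),
               c(-1.3 * 0.4 * 0.7, -1.3 * 0.4 * 0.7, 1.3 * 0.4 * 0.7, 0))

  expect_error(p53_rhs(state[1:3], zero), "4 states")
  expect_error(p53_rhs(state, zero[1:5]), "9 parameters")
})

test_that("arginine right-hand side: zero flux, F1 validity, k7 inhibition term", {
  state <- c(A = 800, B = 25, C = 90)
  zero <- rep(0, 16)
  expect_equal(unname(arginine_rhs(state, zero)), rep(0, 3))

  f1 <- get_model("arginine_F1")$default_params
  expect_length(f1, 16)
  expect_equal(unname(f1[c("k1", "k2")]), c(70, 160.5))
  d <- arginine_rhs(state, f1)
  expect_true(all(is.finite(d)) && length(d) == 3)

  # with k7 = 0 the ornithine competitive-inhibition term vanishes: the
  # derivative field matches the F2 variant at every state, and uptake no
  # longer depends on ornithine
  f2 <- get_model("arginine_F2")$default_params
  k7_zero <- f1; k7_zero["k7"] <- 0
  for (s in list(state, c(100, 1, 1), c(0, 50, 200))) {
    expect_equal(arginine_rhs(s, k7_zero), arginine_rhs(s, f2))
  }
  dB_hi <- arginine_rhs(c(800, 60, 90), f2)
  dB_lo <- arginine_rhs(c(800, 60, 90), f1)
  expect_gt(dB_hi[["C"]], dB_lo[["C"]])  # inhibition throttles uptake into C

  expect_error(arginine_rhs(state[1:2], f1), "3 states")
  expect_error(arginine_rhs(state, f1[1:10]), "16 parameters")
})

test_that("perturbation registry realizes the documented variants", {
  e1 <- get_model("p53_E1")
  e2 <- get_model("p53_E2")
  expect_equal(e2$default_params[c("k4", "k9")], c(k4 = 0, k9 = 0))
  expect_equal(e2$default_params[setdiff(names(e1$default_params), c("k4", "k9"))],
               e1$default_params[setdiff(names(e1$default_params), c("k4", "k9"))])

  f1 <- get_model("arginine_F1")
  # empty override is the identity
  expect_equal(apply_perturbation(f1, list())$default_params, f1$default_params)

  f3 <- get_model("arginine_F3")
  expect_equal(unname(f3$default_params[c("k8", "k15", "k16")]), c(100, 1, 1))
  f4 <- get_model("arginine_F4")
  expect_equal(unname(f4$default_params[c("k7", "k10", "k14", "k15")]), rep(1, 4))
  f5 <- get_model("arginine_F5")
  expect_equal(unname(f5$default_params[c("k2", "k5", "k8", "k15", "k16")]), rep(1, 5))

  # idempotence and base immutability
  ov <- list(k4 = 0, k9 = 0)
  once <- apply_perturbation(e1, ov)
  expect_equal(apply_perturbation(once, ov)$default_params, once$default_params)
  expect_equal(get_model("p53_E1")$default_params["k4"], c(k4 = 0.1))

  expect_error(apply_perturbation(e1, list(k42 = 1)), "unknown parameter")
})

test_that("integration: constant field, closed-form decay, determinism", {
  m <- get_model("p53_E1")
  tr <- integrate_model(m, rep(0, 9), times = seq(0, 10, length.out = 7))
  expect_equal(unname(tr$states),
               matrix(rep(m$initial_state, each = 7), nrow = 7), tolerance = 1e-9)

  dm <- decay_model()
  times <- seq(0, 5, length.out = 20)
  tr <- integrate_model(dm, 0.7, times = times)
  expect_equal(as.numeric(tr$states), 2 * exp(-0.7 * times), tolerance = 1e-7)

  t1 <- integrate_model(m, m$default_params)
  t2 <- integrate_model(m, m$default_params)
  expect_identical(t1$states, t2$states)
})

test_that("compiled derivatives agree with the reference R implementation", {
  for (nm in c("p53_E1", "arginine_F1")) {
    m <- get_model(nm)
    m_r <- m; m_r$compiled <- NULL
    tc <- integrate_model(m, m$default_params)
    tr <- integrate_model(m_r, m$default_params)
    expect_equal(tc$states, tr$states, tolerance = 1e-9)
  }
})

test_that("tolerance refinement changes trajectories by less than the coarse tolerance", {
  m <- get_model("p53_E1")
  coarse <- integrate_model(m, m$default_params, rtol = 1e-8, atol = 1e-10)
  fine <- integrate_model(m, m$default_params, rtol = 1e-9, atol = 1e-11)
  expect_lt(max(abs(coarse$states - fine$states)), 1e-8)
})

test_that("integration failure and negative-concentration flagging are reported", {
  bm <- blowup_model()
  expect_error(integrate_model(bm, 50), class = "fireflyde_integration_failure")
  err <- tryCatch(integrate_model(bm, 50), condition = function(e) e)
  expect_equal(err$params, 50)

  # pure sink crossing zero triggers the negative-concentration warning
  sink <- ode_model("sink", "S", "r",
                    rhs = function(state, params, t = 0, input = NULL) c(S = -params[[1]]),
                    initial_state = 0.05, observed = 1L, bounds = cbind(0, 10))
  expect_warning(integrate_model(sink, 1, times = seq(0, 1, length.out = 5)),
                 "negative")
})

test_that("model constructor enforces its invariants", {
  expect_error(ode_model("m", c("a", "b"), "k", function(s, p, t, u) s,
                         initial_state = 1, observed = 1, bounds = cbind(0, 1)),
               "one entry per state")
  expect_error(ode_model("m", "a", "k", function(s, p, t, u) s,
                         initial_state = 1, observed = integer(0), bounds = cbind(0, 1)),
               "non-empty")
  expect_error(ode_model("m", "a", "k", function(s, p, t, u) s,
                         initial_state = 1, observed = 1, bounds = cbind(2, 1)),
               "lower bound")
  expect_error(get_model("nope"), "unknown model")
})
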