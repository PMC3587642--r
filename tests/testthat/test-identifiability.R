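test_that("residuals are the naive per-entry subtraction", {
  m <- get_model("arginine_F1")
  ds <- generate_dataset(m, times = seq(0, 5, length.out = 5),
                         level = 0.25, seed = 13)
  params <- m$default_params * 0.9
  res <- compute_residuals(params, m, ds)
  pred <- integrate_model(m, params, ds$times)
  for (n in 1:5)
    for (k in 1:2)
      expect_equal(res[n, k], ds$observations[n, k] - pred$states[n, k])

  # residuals under the true parameters on noiseless data vanish
  ds0 <- generate_dataset(m, level = 0, seed = 1)
  expect_lt(max(abs(compute_residuals(m$default_params, m, ds0))), 1e-6)

  # linearity in the data: shifting y shifts residuals by the same constant
  ds_shift <- ds
  ds_shift$observations <- ds$observations + 3
  expect_equal(compute_residuals(params, m, ds_shift), res + 3)
})

test_that("variance point is the mean squared residual", {
  expect_equal(variance_point(rep(0, 10)), 0)
  expect_equal(variance_point(c(1, -1)), 1)
  set.seed(42)
  draws <- rnorm(10000, sd = 2)
  expect_equal(variance_point(draws), 4, tolerance = 0.05)
  # optional degrees-of-freedom correction
  expect_equal(variance_point(c(1, -1, 2), correction = 1),
               sum(c(1, 1, 4)) / 2)
  expect_error(variance_point(numeric(0)), "at least 2")
})

test_that("variance interval matches the chi-square quantile oracle", {
  expect_equal(as.numeric(variance_interval(0, 50)), c(0, 0))

  ci <- variance_interval(1, 100, 0.95)
  expect_equal(as.numeric(ci), c(100 / qchisq(0.975, 100), 100 / qchisq(0.025, 100)))
  expect_equal(as.numeric(ci), c(0.7718, 1.3474), tolerance = 1e-4)
  expect_equal(attr(ci, "chi2_quantiles"), c(74.2219, 129.561), tolerance = 1e-4)

  # interval brackets the point and tightens as N grows
  widths <- sapply(c(1e2, 1e4, 1e6), function(N) {
    ci <- variance_interval(2.5, N, 0.95)
    expect_lte(ci[["lower"]], 2.5)
    expect_gte(ci[["upper"]], 2.5)
    ci[["upper"]] - ci[["lower"]]
  })
  expect_true(all(diff(widths) < 0))

  expect_error(variance_interval(1, 1), "N")
  expect_error(variance_interval(1, 100, 1.2), "gamma")
  expect_error(variance_interval(-1, 100), "xi")
})

test_that("the chi-square verdict reproduces the published pass/fail logic", {
  # an accurate fit: real variance inside the interval
  expect_true(chi2_identifiability_test(3.52e-1, c(3.28e-1, 3.79e-1), 3.53e-1))
  # an overfitted estimate: tiny variance point, interval far below truth
  expect_false(chi2_identifiability_test(5.07e-4, c(4.71e-4, 5.46e-4), 3.53e-1))
  # boundary is inclusive
  expect_true(chi2_identifiability_test(1, c(0.8, 1.3), 0.8))
  expect_true(chi2_identifiability_test(1, c(0.8, 1.3), 1.3))
})

test_that("under the true parameters the variance point equals the realized noise variance", {
  m <- get_model("p53_E1")
  ds <- generate_dataset(m, level = 0.25, seed = 17)
  rep <- identify_model(m$default_params, m, ds)
  expect_equal(rep$table$variance_point,
               unname(ds$realized_noise_var), tolerance = 1e-8)
  expect_true(rep$passed)

  # with more samples the variance point approaches the theoretical variance
  err <- sapply(c(100, 10000), function(n) {
    dsn <- generate_dataset(m, times = seq(0, 30, length.out = n),
                            level = 0.25, seed = 23)
    xi <- variance_point(compute_residuals(m$default_params, m, dsn))
    max(abs(xi - dsn$noise_sd^2) / dsn$noise_sd^2)
  })
  expect_lt(err[2], err[1])
})

test_that("overfitting (variance point far below truth) fails the test", {
  # emulate a noise-chasing fit: residual variance a tiny fraction of truth
  sigma2 <- 0.35
  xi <- sigma2 / 500
  ci <- variance_interval(xi, 200, 0.95)
  expect_false(chi2_identifiability_test(xi, ci, sigma2))
})
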