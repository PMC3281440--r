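test_that("descriptive summary reproduces the survey triple on a constrained census", {
  s <- summarize_counts(census_fixed)
  expect_equal(s$n_hosts, 30)
  expect_equal(s$n_infested, 12)
  expect_equal(s$prevalence, 0.40)
  expect_equal(s$total, 468)
  expect_equal(s$mean_intensity, 39.0)
  expect_equal(s$mean_abundance, 15.6)
  expect_equal(unname(s$count_range), c(7, 83))
})

test_that("summary handles uninfested and uniform censuses", {
  s0 <- summarize_counts(c(0, 0, 0, 0))
  expect_equal(s0$prevalence, 0)
  expect_equal(s0$mean_abundance, 0)
  expect_true(is.na(s0$mean_intensity))
  expect_true(is.na(s0$variance_to_mean))

  s7 <- summarize_counts(c(7, 7, 7, 7))
  expect_equal(s7$prevalence, 1)
  expect_equal(s7$mean_intensity, 7)
  expect_equal(s7$mean_abundance, 7)
  expect_equal(s7$variance_to_mean, 0)

  expect_error(summarize_counts(numeric(0)), "no hosts")
  expect_error(summarize_counts(c(1, -2)), "non-negative")
  expect_error(summarize_counts(c(1, 2.5)), "non-negative")
})

test_that("abundance = prevalence x intensity for any census with infested hosts", {
  for (seed in 1:20) {
    x <- simulate_host_counts(50, mean = 8, k = 0.4, seed = seed)
    if (all(x == 0)) next
    s <- summarize_counts(x)
    expect_equal(s$mean_abundance, s$prevalence * s$mean_intensity)
  }
})

test_that("moment estimator of k equals its closed form and rejects non-overdispersion", {
  for (seed in 1:20) {
    x <- simulate_host_counts(200, mean = 12, k = 0.7, seed = 100 + seed)
    if (stats::var(x) <= mean(x)) next
    fit <- fit_negbin_moments(x)
    expect_equal(fit$k, mean(x)^2 / (stats::var(x) - mean(x)))
    expect_identical(fit$method, "moments")
    expect_true(fit$converged)
  }
  # variance <= mean: moment fit undefined
  expect_error(fit_negbin_moments(rep(c(1, 2), 50)), "overdispersion")
  expect_error(fit_negbin_moments(c(5)), "two hosts")
})

test_that("moment estimator recovers k in a parameter-recovery simulation", {
  x <- simulate_host_counts(1000, mean = 15, k = 0.5, seed = 11)
  expect_lt(abs(fit_negbin_moments(x)$k - 0.5), 0.15)
})

test_that("ML estimator recovers a strongly aggregated k and matches an independent fitter", {
  x <- simulate_host_counts(1000, mean = 15.6, k = 0.12, seed = 42)
  fit <- fit_negbin_mle(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$k - 0.12), 0.04)
  expect_true(is.finite(fit$loglik))
  # independent cross-check: full ML over (size, mu)
  ref <- suppressWarnings(MASS::fitdistr(x, "negative binomial"))
  expect_equal(fit$k, unname(ref$estimate["size"]), tolerance = 1e-3)
  expect_equal(fit$mean, mean(x))
})

test_that("moment and ML estimates agree on a large well-behaved sample", {
  x <- simulate_host_counts(1e4, mean = 10, k = 1, seed = 5)
  km <- fit_negbin_moments(x)$k
  kl <- fit_negbin_mle(x)$k
  expect_lt(abs(km - kl) / kl, 0.10)
})

test_that("ML fit refuses degenerate and Poisson-like samples honestly", {
  expect_error(fit_negbin_mle(rep(4, 50)), "equal")
  # underdispersed sample: no interior maximum, flagged not silently returned
  underdispersed <- rep(c(9, 10, 11), 100)
  expect_warning(fit <- fit_negbin_mle(underdispersed), "not overdispersed")
  expect_false(fit$converged)
  expect_true(is.na(fit$k))
})
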