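test_that("count generator is a pure function of parameters and seed", {
  a <- simulate_host_counts(200, mean = 15.6, k = 0.12, seed = 1)
  b <- simulate_host_counts(200, mean = 15.6, k = 0.12, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, simulate_host_counts(200, 15.6, 0.12, seed = 2)))
  expect_error(simulate_host_counts(0, 15.6, 0.12, 1), "n_hosts")
  expect_error(simulate_host_counts(10, -1, 0.12, 1), "mean")
  expect_error(simulate_host_counts(10, 15.6, 0, 1), "k")
})

test_that("simulated counts converge to the negative-binomial moments", {
  x <- simulate_host_counts(1e5, mean = 15.6, k = 0.12, seed = 123)
  expect_lt(abs(mean(x) - 15.6) / 15.6, 0.02)
  vmr <- stats::var(x) / mean(x)
  expect_lt(abs(vmr - (1 + 15.6 / 0.12)) / (1 + 15.6 / 0.12), 0.10)
})

test_that("very large k approaches the Poisson limit", {
  x <- simulate_host_counts(1e5, mean = 15.6, k = 1e6, seed = 124)
  expect_lt(abs(stats::var(x) / mean(x) - 1), 0.05)
})

test_that("constrained census fixture satisfies the survey summary for any seed", {
  for (seed in 1:10) {
    x <- fixture_census(seed = seed)
    expect_length(x, 30)
    expect_equal(sum(x > 0), 12)
    expect_equal(sum(x), 468)
    expect_true(all(x[x > 0] >= 7 & x[x > 0] <= 83))
    s <- summarize_counts(x)
    expect_equal(s$prevalence, 0.40)
    expect_equal(s$mean_intensity, 39.0)
    expect_equal(s$mean_abundance, 15.6)
  }
  expect_identical(fixture_census(seed = 3), fixture_census(seed = 3))
  vecs <- vapply(1:10, function(s) paste(fixture_census(seed = s),
                                         collapse = ","), character(1))
  expect_gt(length(unique(vecs)), 1)
  expect_error(fixture_census(1, n_infested = 2, total = 468,
                              min_count = 7, max_count = 83), "infeasible")
})

test_that("rearing cohort honors the truncated-normal stage durations", {
  cohort <- simulate_rearing_cohort(stage_schedule(), n = 1e4, seed = 31)
  # oracle: numerically integrated mean of the truncated normal, not the
  # nominal 5.25 (truncation to [4, 7] shifts it)
  dens <- function(t) stats::dnorm(t, 5.25, 0.97) /
    (stats::pnorm(7, 5.25, 0.97) - stats::pnorm(4, 5.25, 0.97))
  mu_trunc <- integrate(function(t) t * dens(t), 4, 7)$value
  expect_lt(abs(mean(cohort$egg) - mu_trunc), 0.1)
  expect_true(all(cohort$egg >= 4 & cohort$egg <= 7))
  expect_true(all(cohort$nymph3 >= 5 & cohort$nymph3 <= 7, na.rm = TRUE))
  # sex assignment tracks the female fraction
  expect_lt(abs(mean(cohort$sex == "female") - 1.3 / 2.3), 0.02)
  expect_identical(cohort, simulate_rearing_cohort(stage_schedule(),
                                                   n = 1e4, seed = 31))
})

test_that("degenerate schedules produce degenerate cohorts", {
  sch <- degenerate_schedule()
  cohort <- simulate_rearing_cohort(sch, n = 200, seed = 8)
  expect_true(all(cohort$egg == 5))
  expect_true(all(cohort$nymph3 == 6))
  # survival 1: everyone reaches adulthood
  expect_true(all(is.na(cohort$died_in_stage)))
  # zero egg rate: no eggs laid
  sch0 <- degenerate_schedule(eggs_per_day = 0)
  c0 <- simulate_rearing_cohort(sch0, n = 200, seed = 8)
  expect_true(all(c0$eggs_laid == 0))
})

test_that("death placement and egg counts respect the record invariants", {
  sch <- degenerate_schedule(stage_survival = c(egg = 0.7, nymph1 = 0.8,
                                                nymph2 = 0.9, nymph3 = 0.95))
  cohort <- simulate_rearing_cohort(sch, n = 2000, seed = 12)
  died <- !is.na(cohort$died_in_stage)
  expect_gt(sum(died), 0)
  # died-in stage and later durations are absent
  expect_true(all(is.na(cohort$nymph1[cohort$died_in_stage %in% "nymph1"])))
  expect_true(all(is.na(cohort$adult_lifespan[died])))
  # males and immature deaths never lay
  expect_true(all(cohort$eggs_laid[cohort$sex == "male"] == 0))
  expect_true(all(cohort$eggs_laid[died] == 0))
  # egg-stage deaths die at the end of incubation (5 days here)
  expect_true(all(cohort$death_age[cohort$died_in_stage %in% "egg"] == 5))
})

test_that("empirical life table equals the analytic one for a deterministic cohort", {
  sch <- degenerate_schedule(stage_means = c(5.25, 5.08, 5.54, 6.04),
                             female_lifespan = 15, eggs_per_day = 0)
  lt_a <- build_life_table(sch)
  cohort <- simulate_rearing_cohort(sch, n = 50, seed = 3)
  lt_e <- cohort_to_life_table(cohort)
  expect_equal(nrow(lt_a), nrow(lt_e))
  expect_equal(lt_a$lx, lt_e$lx)
  expect_equal(lt_a$mx, lt_e$mx)  # both zero: no egg laying
  # with egg laying on, survivorship still matches exactly
  sch2 <- degenerate_schedule(stage_means = c(5.25, 5.08, 5.54, 6.04),
                              female_lifespan = 15, eggs_per_day = 0.35)
  lt_e2 <- cohort_to_life_table(simulate_rearing_cohort(sch2, 50, seed = 3))
  expect_equal(build_life_table(sch2)$lx, lt_e2$lx)
})

test_that("cohort without females cannot yield fecundity", {
  cohort <- simulate_rearing_cohort(stage_schedule(), n = 50, seed = 4)
  males <- cohort[cohort$sex == "male", ]
  attr(males, "schedule") <- attr(cohort, "schedule")
  expect_error(cohort_to_life_table(males), "no females")
})

test_that("aggregation round-trip: ML fit recovers the generating k", {
  errs <- vapply(1:20, function(i) {
    x <- simulate_host_counts(500, mean = 15.6, k = 0.5, seed = 4000 + i)
    abs(fit_negbin_mle(x)$k - 0.5) / 0.5
  }, numeric(1))
  expect_lt(stats::median(errs), 0.20)
})
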