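test_that("rectangular survivorship gives R0 = lifespan x daily fecundity", {
  # zero-variance 5+5+5+6 day development, exactly 10 adult days
  sch <- degenerate_schedule(stage_means = c(5, 5, 5, 6), female_lifespan = 10,
                             eggs_per_day = 0.2, female_fraction = 0.5)
  lt <- build_life_table(sch)
  mx_adult <- 0.2 * 0.5
  expect_true(all(lt$lx[lt$x <= 21] == 1))
  expect_equal(net_reproductive_rate(lt), 10 * mx_adult)
  expect_true(all(lt$mx[lt$x < 21] == 0))
  expect_true(all(lt$mx[lt$x >= 21] == mx_adult))
})

test_that("life table from the rearing calibration behaves as an expected cohort", {
  lt <- build_life_table(stage_schedule())
  expect_equal(lt$lx[1], 1)
  expect_true(all(diff(lt$lx) <= 1e-12))
  expect_true(all(lt$mx[lt$x < 22] == 0))       # emergence at day 22
  expect_equal(max(lt$mx), 0.35 * 1.3 / 2.3)
  # summed adult survivorship equals the expected adult lifespan
  # (numerically integrated survival of the truncated lifespan distribution)
  expected_lifespan <- integrate(function(t)
    lousepop:::tnorm_sf(t, 15, 6.28, 2, 24), 0, 24)$value
  expect_equal(sum(lt$lx[lt$x >= 22]), expected_lifespan, tolerance = 0.02)
  d <- demography(lt)
  expect_equal(exp(d$rm * d$T), d$R0, tolerance = 1e-8)
})

test_that("zero egg-stage survival gives an extinct cohort", {
  sch <- degenerate_schedule(stage_survival = c(egg = 0, nymph1 = 1,
                                                nymph2 = 1, nymph3 = 1))
  lt <- build_life_table(sch)
  expect_true(all(lt$lx[lt$x >= 5] == 0))
  expect_equal(net_reproductive_rate(lt), 0)
  expect_error(solve_rm(lt), "no root")
})

test_that("max_age must contain reproduction", {
  expect_error(build_life_table(stage_schedule(), max_age = 25), "max_age")
})

test_that("point-mass cohorts solve the Euler-Lotka equation in closed form", {
  lt <- life_table(0:10, rep(1, 11), c(rep(0, 10), 2))
  expect_equal(solve_rm(lt), log(2) / 10, tolerance = 1e-10)
  expect_equal(net_reproductive_rate(lt), 2)
  # replacement-level cohort: R0 = 1 => rm = 0
  lt1 <- life_table(0:10, rep(1, 11), c(rep(0, 10), 1))
  expect_lt(abs(solve_rm(lt1)), 1e-8)
  # declining cohort: rm < 0
  lt_neg <- life_table(0:10, rep(1, 11), c(rep(0, 10), 0.5))
  expect_equal(solve_rm(lt_neg), log(0.5) / 10, tolerance = 1e-10)
})

test_that("solver residual meets tolerance and matches the grid-scan oracle", {
  for (seed in 1:10) {
    lt <- random_life_table(700 + seed)
    rm <- solve_rm(lt)
    w <- lt$lx * lt$mx
    expect_lt(abs(sum(exp(-rm * lt$x) * w) - 1), 1e-10)
    expect_lt(abs(rm - rm_grid_scan(lt)), 1e-4)
  }
})

test_that("discounted reproduction is strictly decreasing in r (root unique)", {
  for (seed in 1:10) {
    lt <- random_life_table(800 + seed)
    w <- lt$lx * lt$mx
    rs <- seq(-0.5, 0.5, length.out = 101)
    vals <- vapply(rs, function(r) sum(exp(-r * lt$x) * w), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("sign law: rm > 0 iff R0 > 1", {
  for (seed in 1:20) {
    lt <- random_life_table(900 + seed)
    R0 <- net_reproductive_rate(lt)
    rm <- solve_rm(lt)
    expect_equal(sign(rm), sign(R0 - 1))
  }
})

test_that("generation and doubling times follow their closed forms", {
  expect_equal(generation_time(3.67, 0.035), log(3.67) / 0.035)
  expect_equal(generation_time(exp(1), 1), 1)
  expect_error(generation_time(3.67, 0), "rm = 0")
  expect_error(generation_time(0, 0.035), "positive")

  expect_equal(doubling_time(log(2)), 1)
  expect_error(doubling_time(0), "not growing")
  expect_error(doubling_time(-0.01), "not growing")

  # point-mass cohort at age a: T = a exactly
  lt <- life_table(0:8, rep(1, 9), c(rep(0, 8), 3))
  rm <- solve_rm(lt)
  expect_equal(generation_time(3, rm), 8, tolerance = 1e-8)

  # DT < T iff R0 > 2 (both equal log(R0 or 2)/rm)
  expect_lt(doubling_time(rm), generation_time(3, rm))
  lt2 <- life_table(0:8, rep(1, 9), c(rep(0, 8), 1.5))
  rm2 <- solve_rm(lt2)
  expect_gt(doubling_time(rm2), generation_time(1.5, rm2))
})

test_that("demography() bundles consistent results", {
  lt <- random_life_table(77)
  d <- demography(lt)
  expect_equal(d$R0, net_reproductive_rate(lt))
  expect_equal(d$lam, exp(d$rm))
  expect_equal(exp(d$rm * d$T), d$R0, tolerance = 1e-8)
  if (d$rm > 0) expect_equal(d$DT, log(2) / d$rm)
})

test_that("life-table constructor enforces its invariants", {
  expect_error(life_table(0:2, c(1, 0.5, 0.6), c(0, 0, 0)), "non-increasing")
  expect_error(life_table(0:2, c(0.9, 0.5, 0.2), c(0, 0, 0)), "start at 1")
  expect_error(life_table(1:3, c(1, 0.5, 0.2), c(0, 0, 0)), "start at 0")
  expect_error(life_table(0:2, c(1, 0.5, 0.2), c(0, -1, 0)), "non-negative")
  expect_error(life_table(0:2, c(1, 0.5), c(0, 0, 0)), "equal length")
})
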