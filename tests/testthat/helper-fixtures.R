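# Shared fixtures and independent oracles, all built in code.

# Hand-built 30-host census: 18 uninfested, 12 positive counts in [7, 83]
# summing to 468 (prevalence 0.40, mean intensity 39.0, abundance 15.6).
census_fixed <- c(rep(0, 18),
                  7, 10, 14, 19, 25, 31, 38, 46, 55, 65, 75, 83)

# Zero-variance schedule: every duration pinned at its mean; useful for
# rectangular-survivorship and cross-module equivalence checks.
degenerate_schedule <- function(stage_means = c(5, 5, 5, 6),
                                female_lifespan = 10,
                                eggs_per_day = 0.2,
                                female_fraction = 0.5,
                                stage_survival = c(egg = 1, nymph1 = 1,
                                                   nymph2 = 1, nymph3 = 1)) {
  stage_schedule(
    stages = data.frame(stage = c("egg", "nymph1", "nymph2", "nymph3"),
                        mean = stage_means, sd = 0,
                        min = stage_means, max = stage_means,
                        stringsAsFactors = FALSE),
    adult_female = c(mean = female_lifespan, sd = 0,
                     min = female_lifespan, max = female_lifespan),
    adult_male = c(mean = 8, sd = 0, min = 8, max = 8),
    eggs_per_female_day = eggs_per_day,
    lifetime_eggs_per_female = eggs_per_day * female_lifespan,
    female_fraction = female_fraction,
    stage_survival = stage_survival
  )
}

# Independent brute-force oracle for the index of discrepancy, via the
# pairwise mean-absolute-difference Gini coefficient:
#   D = N/(N+1) * Gini,  Gini = sum_ij |x_i - x_j| / (2 N^2 mean)
# (a different derivation route than the cumulative-sum formula).
discrepancy_bruteforce <- function(x) {
  n <- length(x)
  gini <- sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  n * gini / (n + 1)
}

# All count vectors of length `len` with total <= `max_total` and at
# least one positive entry, as a matrix (one row per vector).
enumerate_count_vectors <- function(len, max_total) {
  g <- as.matrix(expand.grid(rep(list(0:max_total), len)))
  g[rowSums(g) <= max_total & rowSums(g) > 0, , drop = FALSE]
}

# Random valid life table with reproduction spread over several ages.
random_life_table <- function(seed) {
  withr::with_seed(seed, {
    amax <- sample(15:40, 1)
    x <- 0:amax
    lx <- c(1, cumprod(stats::runif(amax, 0.85, 1)))
    first_rep <- sample(3:10, 1)
    mx <- ifelse(x >= first_rep, stats::runif(amax + 1, 0, 0.4), 0)
    life_table(x, lx, mx)
  })
}

# Grid-scan oracle for the Euler-Lotka root: the discounted-reproduction
# function f(r) is strictly decreasing, so its unique sign change on the
# step-1e-5 grid over [-1, 1] is located with a coarse pass (step 1e-2)
# followed by the full fine scan inside the bracketing coarse cell.
# No root finder is used.
rm_grid_scan <- function(lt, step = 1e-5) {
  w <- lt$lx * lt$mx
  keep <- w > 0
  xs <- lt$x[keep]
  w <- w[keep]
  f_at <- function(r) colSums(w * exp(-outer(xs, r))) - 1
  coarse <- seq(-1, 1, by = 1e-2)
  fc <- f_at(coarse)
  i <- which(fc > 0 & c(fc[-1], -Inf) <= 0)[1]
  stopifnot(is.finite(i))
  fine <- seq(coarse[i], coarse[i + 1], by = step)
  ff <- f_at(fine)
  fine[which.min(abs(ff))]
}
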