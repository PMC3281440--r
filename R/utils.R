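# Truncated-normal helpers shared by the life-table builder and the cohort
# simulator. sd = 0 is allowed and collapses to a point mass at `mean`.

tnorm_check <- function(mean, sd, lo, hi) {
  if (!is.finite(mean) || !is.finite(sd) || !is.finite(lo) || !is.finite(hi))
    stop("truncated-normal parameters must be finite", call. = FALSE)
  if (lo > hi)
    stop("impossible truncation bounds: min > max", call. = FALSE)
  if (sd < 0)
    stop("sd must be >= 0", call. = FALSE)
  if (sd == 0 && (mean < lo || mean > hi))
    stop("degenerate distribution (sd = 0) has its mean outside [min, max]",
         call. = FALSE)
  if (sd > 0) {
    z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
    if (z <= 0)
      stop("truncation interval [min, max] carries no probability mass",
           call. = FALSE)
  }
  invisible(TRUE)
}

# Inverse-CDF sampler; deterministic given the RNG state.
rtnorm <- function(n, mean, sd, lo, hi) {
  tnorm_check(mean, sd, lo, hi)
  if (sd == 0) return(rep(mean, n))
  fa <- stats::pnorm(lo, mean, sd)
  fb <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, fa, fb)
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

# Closed-form mean of the truncated normal.
tnorm_mean <- function(mean, sd, lo, hi) {
  tnorm_check(mean, sd, lo, hi)
  if (sd == 0) return(mean)
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Survival function P(X > t) of the truncated normal.
tnorm_sf <- function(t, mean, sd, lo, hi) {
  tnorm_check(mean, sd, lo, hi)
  if (sd == 0) return(as.numeric(t < mean))
  fa <- stats::pnorm(lo, mean, sd)
  fb <- stats::pnorm(hi, mean, sd)
  ft <- stats::pnorm(pmin(pmax(t, lo), hi), mean, sd)
  out <- (fb - ft) / (fb - fa)
  out[t < lo] <- 1
  out[t >= hi] <- 0
  pmin(pmax(out, 0), 1)
}

# Shared validator for per-host count vectors.
check_counts <- function(counts) {
  if (length(counts) == 0)
    stop("no hosts examined: `counts` is empty", call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts))
    stop("`counts` must be a numeric vector without missing values",
         call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("`counts` must contain non-negative integers (parasites per host)",
         call. = FALSE)
  as.numeric(counts)
}
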