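#' Moment estimator of the negative-binomial exponent k
#'
#' The corrected moment estimator of the aggregation exponent,
#' \eqn{k = \bar{x}^2 / (s^2 - \bar{x})}, defined only for overdispersed
#' samples (sample variance exceeding the sample mean). Smaller `k` means
#' stronger aggregation of parasites on few hosts.
#'
#' @param counts Numeric vector of non-negative integer counts per host
#'   (at least two hosts).
#' @return An object of class `"negbin_fit"`: a list with elements `k`,
#'   `mean` (the sample mean), `method = "moments"`, `loglik` (`NA` for the
#'   moment fit) and `converged`.
#' @examples
#' x <- rnbinom(200, size = 0.5, mu = 15)
#' fit_negbin_moments(x)
#' @seealso [fit_negbin_mle()] for the maximum-likelihood estimator.
#' @export
fit_negbin_moments <- function(counts) {
  x <- check_counts(counts)
  if (length(x) < 2)
    stop("at least two hosts are needed to estimate a variance", call. = FALSE)
  m <- mean(x)
  v <- stats::var(x)
  if (v <= m)
    stop("no overdispersion: sample variance <= mean, ",
         "the negative-binomial moment estimator of k is undefined",
         call. = FALSE)
  structure(list(
    k = m^2 / (v - m),
    mean = m,
    method = "moments",
    loglik = NA_real_,
    converged = TRUE
  ), class = "negbin_fit")
}

#' Maximum-likelihood estimator of the negative-binomial exponent k
#'
#' Fits the negative binomial to per-host counts by maximising the
#' log-likelihood in the exponent `k` with the mean fixed at the sample mean
#' (which is itself the maximum-likelihood estimate of the mean). The score
#' equation
#' \deqn{\sum_i \psi(x_i + k) - n\,\psi(k) + n \log\frac{k}{k + \bar{x}} = 0}
#' (\eqn{\psi} the digamma function) is solved by bracketing and bisection on
#' the logarithmic scale. The score is positive as `k` tends to 0 and, for an
#' overdispersed sample, becomes negative for large `k`, so the bracketed
#' root is the unique interior maximum.
#'
#' For samples without aggregation signal (variance at or below the mean) the
#' likelihood increases towards `k = Inf` and no interior maximum exists; the
#' fit is then returned with `converged = FALSE` and `k = NA`. A sample of
#' identical counts is rejected outright.
#'
#' @param counts Numeric vector of non-negative integer counts per host.
#' @param tol Relative width of the final bisection bracket; convergence
#'   tolerance on `k`.
#' @param max_iter Iteration cap for the bisection; if reached, the result is
#'   flagged `converged = FALSE`.
#' @return An object of class `"negbin_fit"`: a list with elements `k`,
#'   `mean`, `method = "mle"`, `loglik` (the maximised log-likelihood) and
#'   `converged`.
#' @examples
#' x <- simulate_host_counts(500, mean = 15.6, k = 0.5, seed = 1)
#' fit_negbin_mle(x)
#' @export
fit_negbin_mle <- function(counts, tol = 1e-8, max_iter = 200L) {
  x <- check_counts(counts)
  n <- length(x)
  m <- mean(x)
  if (m <= 0)
    stop("maximum-likelihood fit requires a positive sample mean",
         call. = FALSE)
  if (all(x == x[1]))
    stop("all counts are equal: the likelihood has no interior maximum in k",
         call. = FALSE)
  stopifnot(tol > 0, max_iter >= 1)

  score <- function(k) sum(digamma(x + k)) - n * digamma(k) + n * log(k / (k + m))
  loglik <- function(k) sum(stats::dnbinom(x, size = k, mu = m, log = TRUE))

  # an interior maximum in k exists iff the (biased) sample variance
  # exceeds the mean; otherwise the likelihood increases towards k = Inf
  v_ml <- mean(x^2) - m^2
  lo <- 1e-10
  hi <- 1
  if (v_ml > m) while (score(hi) > 0 && hi < 1e12) hi <- hi * 4
  if (v_ml <= m || score(hi) > 0) {
    # likelihood still increasing at very large k: Poisson-like sample
    warning("no interior maximum found: counts are not overdispersed; ",
            "returning converged = FALSE", call. = FALSE)
    return(structure(list(k = NA_real_, mean = m, method = "mle",
                          loglik = NA_real_, converged = FALSE),
                     class = "negbin_fit"))
  }

  iter <- 0L
  converged <- FALSE
  mid <- sqrt(lo * hi)
  while (iter < max_iter) {
    iter <- iter + 1L
    mid <- sqrt(lo * hi)  # bisect on the log scale: k spans many decades
    if (score(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) < tol * (1 + hi)) {
      converged <- TRUE
      break
    }
  }
  k <- sqrt(lo * hi)
  structure(list(k = k, mean = m, method = "mle",
                 loglik = loglik(k), converged = converged),
            class = "negbin_fit")
}

#' @export
print.negbin_fit <- function(x, ...) {
  cat(sprintf("Negative-binomial fit (%s)\n", x$method))
  cat(sprintf("  k = %s   mean = %.4g   converged: %s\n",
              if (is.na(x$k)) "NA" else sprintf("%.4g", x$k),
              x$mean, x$converged))
  if (!is.na(x$loglik))
    cat(sprintf("  log-likelihood = %.4f\n", x$loglik))
  invisible(x)
}

#' Chi-squared goodness of fit of counts to a fitted negative binomial
#'
#' Compares the observed frequency distribution of per-host counts with the
#' frequencies expected under a fitted negative binomial. Count classes are
#' the integers `0, 1, 2, ...` up to one below the maximum observed count,
#' plus a single open upper tail; adjacent classes are pooled from the tail
#' inward until every expected class frequency reaches `min_expected`.
#' The statistic is \eqn{\chi^2 = \sum (O - E)^2 / E} with
#' `df = classes - 3` (two parameters, mean and `k`, were estimated).
#'
#' @param counts Numeric vector of non-negative integer counts per host.
#' @param fit A `"negbin_fit"` object (from [fit_negbin_mle()] or
#'   [fit_negbin_moments()]) supplying `k` and `mean`.
#' @param min_expected Pooling threshold: minimum expected frequency per
#'   class after pooling. Default 1.
#' @return An object of class `"gof_result"`: a list with elements `chi2`,
#'   `df`, `p_value` and `classes`, a data frame of pooled class labels with
#'   observed and expected frequencies. Expected frequencies sum to the
#'   number of hosts.
#' @examples
#' x <- simulate_host_counts(1000, mean = 10, k = 1, seed = 1)
#' fit <- fit_negbin_mle(x)
#' gof_negbin(x, fit)
#' @export
gof_negbin <- function(counts, fit, min_expected = 1) {
  x <- check_counts(counts)
  stopifnot(inherits(fit, "negbin_fit"))
  if (is.na(fit$k) || fit$k <= 0 || is.na(fit$mean) || fit$mean <= 0)
    stop("`fit` does not carry a valid (k, mean) pair", call. = FALSE)
  if (min_expected <= 0)
    stop("`min_expected` must be positive", call. = FALSE)
  n <- length(x)
  cmax <- max(x)
  if (cmax < 3)
    stop("fewer than 4 count classes are available; ",
         "degrees of freedom would be < 1", call. = FALSE)

  body <- 0:(cmax - 1)
  obs <- c(vapply(body, function(j) sum(x == j), numeric(1)), sum(x >= cmax))
  expd <- c(n * stats::dnbinom(body, size = fit$k, mu = fit$mean),
            n * stats::pnbinom(cmax - 1, size = fit$k, mu = fit$mean,
                               lower.tail = FALSE))
  labels <- c(as.character(body), paste0(">=", cmax))
  tail_start <- cmax

  # pool from the tail inward; never drop below 4 classes (df >= 1)
  while (any(expd < min_expected)) {
    if (length(expd) <= 4)
      stop("cannot pool count classes to expected >= min_expected ",
           "without dropping below 4 classes (df < 1)", call. = FALSE)
    nc <- length(expd)
    obs <- c(obs[1:(nc - 2)], obs[nc - 1] + obs[nc])
    expd <- c(expd[1:(nc - 2)], expd[nc - 1] + expd[nc])
    tail_start <- tail_start - 1L
    labels <- c(labels[1:(nc - 2)], paste0(">=", tail_start))
  }

  chi2 <- sum((obs - expd)^2 / expd)
  df <- length(expd) - 3L
  structure(list(
    chi2 = chi2,
    df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    classes = data.frame(class = labels, observed = obs, expected = expd,
                         stringsAsFactors = FALSE)
  ), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Chi-squared goodness of fit to the negative binomial\n")
  cat(sprintf("  chi2 = %.4g on %d df, P = %.4g (%d pooled classes)\n",
              x$chi2, x$df, x$p_value, nrow(x$classes)))
  invisible(x)
}
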