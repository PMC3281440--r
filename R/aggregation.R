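#' Descriptive infracommunity statistics for per-host parasite counts
#'
#' Computes the standard descriptive statistics of quantitative parasitology
#' for a vector of parasite counts, one entry per examined host: prevalence
#' (fraction of hosts infested), mean intensity (mean count over infested
#' hosts only), sample mean abundance (mean count over all examined hosts),
#' the unbiased sample variance and the variance-to-mean ratio.
#'
#' The three headline statistics obey the identity
#' `mean_abundance = prevalence * mean_intensity` whenever at least one host
#' is infested. When no host is infested, mean intensity is reported as `NA`
#' (it is undefined, not zero).
#'
#' @param counts Numeric vector of non-negative integer counts, one per
#'   examined host. Names, if present, are treated as host identifiers.
#' @return An object of class `"aggregation_summary"`: a list with elements
#'   `n_hosts`, `n_infested`, `prevalence`, `total`, `mean_intensity`
#'   (`NA` when no host is infested), `mean_abundance`, `count_range`
#'   (minimum positive count and maximum count; `NA`s when no host is
#'   infested), `variance` (unbiased, n - 1 denominator) and
#'   `variance_to_mean` (`NA` when the mean is zero).
#' @examples
#' x <- c(rep(0, 18), 7, 10, 14, 19, 25, 31, 38, 46, 55, 65, 75, 83)
#' summarize_counts(x)
#' @seealso [fit_negbin_mle()], [index_of_discrepancy()]
#' @export
summarize_counts <- function(counts) {
  x <- check_counts(counts)
  n <- length(x)
  pos <- x[x > 0]
  n_inf <- length(pos)
  total <- sum(x)
  m <- total / n
  v <- if (n > 1) stats::var(x) else NA_real_
  structure(list(
    n_hosts = n,
    n_infested = n_inf,
    prevalence = n_inf / n,
    total = total,
    mean_intensity = if (n_inf > 0) total / n_inf else NA_real_,
    mean_abundance = m,
    count_range = if (n_inf > 0) c(min = min(pos), max = max(x))
                  else c(min = NA_real_, max = NA_real_),
    variance = v,
    variance_to_mean = if (m > 0) v / m else NA_real_
  ), class = "aggregation_summary")
}

#' @export
print.aggregation_summary <- function(x, ...) {
  cat("Host-level parasite count summary\n")
  cat(sprintf("  hosts examined : %d (%d infested, prevalence %.1f%%)\n",
              x$n_hosts, x$n_infested, 100 * x$prevalence))
  cat(sprintf("  total parasites: %d (positive counts %s-%s)\n",
              as.integer(x$total), format(x$count_range[["min"]]),
              format(x$count_range[["max"]])))
  cat(sprintf("  mean intensity : %s   mean abundance: %.4g\n",
              if (is.na(x$mean_intensity)) "undefined"
              else sprintf("%.4g", x$mean_intensity),
              x$mean_abundance))
  cat(sprintf("  variance       : %.4g   variance/mean: %s\n",
              x$variance,
              if (is.na(x$variance_to_mean)) "undefined"
              else sprintf("%.4g", x$variance_to_mean)))
  invisible(x)
}

#' Index of discrepancy (D) of a parasite count distribution
#'
#' Poulin's index of discrepancy measures how far the observed distribution
#' of parasites across hosts departs from perfect uniformity: `D = 0` when
#' every host carries the same count and `D` approaches 1 as the whole
#' population concentrates on a single host. With the counts sorted in
#' ascending order over `N` hosts,
#' \deqn{D = 1 - \frac{2 \sum_i c_i}{\bar{x} N (N + 1)}}
#' where \eqn{c_i} is the cumulative sum through host \eqn{i} and
#' \eqn{\bar{x}} the mean count. `D` equals `N/(N+1)` times the Gini
#' coefficient of the counts, is invariant under permutation of hosts and
#' increases under any transfer of a parasite from a poorer to a richer host.
#'
#' @param counts Numeric vector of non-negative integer counts, one per host;
#'   at least one count must be positive.
#' @return The index of discrepancy, a number in `[0, 1)`.
#' @examples
#' index_of_discrepancy(c(0, 0, 0, 10))  # 0.6
#' index_of_discrepancy(c(5, 5, 5, 5))   # 0: perfectly uniform
#' @export
index_of_discrepancy <- function(counts) {
  x <- sort(check_counts(counts))
  if (sum(x) == 0)
    stop("index of discrepancy is undefined when all counts are zero",
         call. = FALSE)
  n <- length(x)
  m <- mean(x)
  1 - 2 * sum(cumsum(x)) / (m * n * (n + 1))
}
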