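#' Net reproductive rate R0
#'
#' The expected number of female eggs a newborn female produces over her
#' lifetime: \eqn{R_0 = \sum_x l_x m_x}.
#'
#' @param lt A [life_table()].
#' @return `R0`, female eggs per female.
#' @export
net_reproductive_rate <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  sum(lt$lx * lt$mx)
}

#' Intrinsic rate of natural increase from the Euler-Lotka equation
#'
#' Solves \eqn{\sum_x e^{-r x} l_x m_x = 1} for the intrinsic rate of
#' natural increase `rm` (per day). The left-hand side is strictly
#' decreasing in `r` whenever any reproduction occurs at a positive age,
#' so the real root is unique. The root is bracketed (starting from
#' `[-2, 2]` and expanding geometrically if needed), located with
#' [stats::uniroot()] and polished by Newton steps until the residual
#' \eqn{|\sum_x e^{-r_m x} l_x m_x - 1|} falls below `tol`. A table whose
#' entire reproduction sits at a single positive age `a` is solved in
#' closed form, `rm = log(R0)/a`.
#'
#' @param lt A [life_table()] with `R0 > 0`.
#' @param tol Residual tolerance; default `1e-10`.
#' @return `rm`, per day. Positive iff `R0 > 1`, zero iff `R0 = 1`.
#' @examples
#' lt <- life_table(0:10, rep(1, 11), c(rep(0, 10), 2))
#' solve_rm(lt)            # log(2)/10
#' @export
solve_rm <- function(lt, tol = 1e-10) {
  stopifnot(inherits(lt, "life_table"), tol > 0)
  w <- lt$lx * lt$mx
  keep <- w > 0
  if (!any(keep))
    stop("R0 = 0: the Euler-Lotka equation has no root", call. = FALSE)
  ages <- lt$x[keep]
  w <- w[keep]
  R0 <- sum(w)
  if (all(ages == 0))
    stop("all reproduction at age 0: the Euler-Lotka equation is degenerate",
         call. = FALSE)
  if (length(ages) == 1L)
    return(log(R0) / ages)

  f <- function(r) sum(exp(-r * ages) * w) - 1
  lo <- -2; hi <- 2
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("failed to bracket the Euler-Lotka root", call. = FALSE)
  }
  while (f(lo) < 0) {
    lo <- lo * 2
    if (lo < -1e6) stop("failed to bracket the Euler-Lotka root", call. = FALSE)
  }
  r <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  for (i in 1:50) {
    fr <- f(r)
    if (abs(fr) < tol) break
    slope <- sum(ages * exp(-r * ages) * w)
    r <- r + fr / slope
  }
  if (abs(f(r)) >= tol)
    stop("Euler-Lotka solver failed to reach the requested residual tolerance",
         call. = FALSE)
  r
}

#' Generation time
#'
#' Mean age of mothers at offspring production in the exponential-growth
#' model: \eqn{T = \ln(R_0) / r_m}, in days. As `rm` tends to 0 this
#' quantity tends to the cohort's mean age of reproduction; at `rm = 0`
#' exactly it is undefined and an error is raised.
#'
#' @param R0 Net reproductive rate, > 0.
#' @param rm Intrinsic rate of natural increase per day, nonzero.
#' @return `T`, days.
#' @examples
#' generation_time(3.67, 0.035)  # 37.15 days
#' @export
generation_time <- function(R0, rm) {
  if (!is.numeric(R0) || R0 <= 0)
    stop("`R0` must be positive", call. = FALSE)
  if (!is.numeric(rm) || rm == 0)
    stop("generation time is undefined at rm = 0 ",
         "(it tends to the mean age of reproduction in that limit)",
         call. = FALSE)
  log(R0) / rm
}

#' Population doubling time
#'
#' Days for a population growing at rate `rm` to double:
#' \eqn{DT = \ln 2 / r_m} (equivalently \eqn{\ln 2 / \ln \lambda} with
#' \eqn{\lambda = e^{r_m}}).
#'
#' @param rm Intrinsic rate of natural increase per day, > 0.
#' @return `DT`, days.
#' @examples
#' doubling_time(log(2))  # 1 day
#' @export
doubling_time <- function(rm) {
  if (!is.numeric(rm) || rm <= 0)
    stop("doubling time is undefined: the population is not growing (rm <= 0)",
         call. = FALSE)
  log(2) / rm
}

#' Demographic parameters of a life table
#'
#' One-call summary: net reproductive rate `R0`, intrinsic rate of natural
#' increase `rm` (Euler-Lotka root), generation time `T = log(R0)/rm`,
#' doubling time `DT = log(2)/rm` (reported as `NA` when the population is
#' not growing) and the finite daily growth rate `lambda = exp(rm)`.
#'
#' @param lt A [life_table()] with `R0 > 0`.
#' @param tol Residual tolerance passed to [solve_rm()].
#' @return An object of class `"demography_result"`: a list with elements
#'   `rm`, `R0`, `T`, `DT`, `lam`. By construction `exp(rm * T) == R0`.
#' @examples
#' demography(build_life_table(stage_schedule()))
#' @export
demography <- function(lt, tol = 1e-10) {
  R0 <- net_reproductive_rate(lt)
  rm <- solve_rm(lt, tol = tol)
  Tg <- if (rm != 0) generation_time(R0, rm) else NA_real_
  DT <- if (rm > 0) doubling_time(rm) else NA_real_
  structure(list(rm = rm, R0 = R0, T = Tg, DT = DT, lam = exp(rm)),
            class = "demography_result")
}

#' @export
print.demography_result <- function(x, ...) {
  cat("Cohort demography\n")
  cat(sprintf("  R0 (net reproductive rate)    : %.4g female eggs/female\n", x$R0))
  cat(sprintf("  rm (intrinsic rate of increase): %.4g /day\n", x$rm))
  cat(sprintf("  lambda (finite rate)          : %.4g /day\n", x$lam))
  cat(sprintf("  T (generation time)           : %s days\n",
              if (is.na(x$T)) "NA" else sprintf("%.4g", x$T)))
  cat(sprintf("  DT (doubling time)            : %s days\n",
              if (is.na(x$DT)) "NA (not growing)" else sprintf("%.4g", x$DT)))
  invisible(x)
}
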