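---
title: "Methods: aggregation statistics and life-table demography in lousepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregation statistics and life-table demography in lousepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lousepop)
```

`lousepop` implements the two quantitative workflows of a field-plus-rearing
study of a chewing louse on a bird host: (i) how the lice are distributed
across hosts, and (ii) how fast a louse population grows given its
developmental and reproductive schedule. This vignette documents the models,
the parameter choices, the numerical details, and what the synthetic-data
generators do and do not emulate.

## 1. Aggregation of parasites across hosts

### Descriptive statistics

For a census of non-negative integer counts $x_1,\dots,x_N$ (lice per
examined host), `summarize_counts()` reports prevalence $p$ (fraction of
hosts with $x_i > 0$), mean intensity $\bar{x}_{+}$ (mean over infested
hosts), sample mean abundance $\bar{x}$ (mean over all hosts), the unbiased
($n-1$ denominator) sample variance, and the variance-to-mean ratio. The
identity $\bar{x} = p\,\bar{x}_{+}$ holds exactly whenever at least one host
is infested; with no infested hosts, mean intensity is reported as `NA`
because a zero would silently propagate into downstream ratios. We fix the
unbiased variance convention once and use it everywhere (the moment
estimator of $k$, the variance-to-mean ratio).

### The negative-binomial exponent $k$

Parasite counts are almost always overdispersed: a few hosts carry most of
the parasites. The standard model is the negative binomial, parameterised by
the mean $\mu$ and the exponent $k > 0$; the variance is
$\mu + \mu^2/k$, so smaller $k$ means stronger aggregation. Two estimators
are provided:

* **Moments** (`fit_negbin_moments()`): $\hat{k} = \bar{x}^2/(s^2-\bar{x})$,
  defined only when $s^2 > \bar{x}$; an error is raised otherwise because
  the closed form is meaningless at or below the Poisson boundary.
* **Maximum likelihood** (`fit_negbin_mle()`), the headline estimator. The
  ML estimate of the negative-binomial mean is the sample mean regardless of
  $k$, so the problem reduces to a one-dimensional profile score in $k$:
  $$U(k) = \sum_i \psi(x_i + k) - n\,\psi(k) + n \log\frac{k}{k+\bar{x}},$$
  with $\psi$ the digamma function. $U$ is positive as $k \to 0^+$ and, for
  an overdispersed sample, negative beyond the optimum, so the root is
  bracketed by geometric expansion and located by bisection on the
  logarithmic scale (tolerance `tol`, default $10^{-8}$; iteration cap
  `max_iter`, default 200, with an honest `converged` flag). An interior
  maximum exists if and only if the biased sample variance exceeds the mean;
  when it does not, the fit returns `converged = FALSE` with `k = NA`
  rather than a spuriously huge $k$ — testing that condition up front also
  avoids the floating-point cancellation that plagues evaluating $U$ at very
  large $k$. A sample of identical counts is rejected outright.

Both estimators are reported by the pipeline; tests cross-check the ML fit
against an independent full-likelihood fitter (`MASS::fitdistr`) and verify
parameter recovery on simulated censuses.

### Index of discrepancy

`index_of_discrepancy()` computes Poulin's $D$: with counts sorted
ascending and $c_i$ the cumulative sum through host $i$,
$$D = 1 - \frac{2\sum_i c_i}{\bar{x}\,N\,(N+1)}.$$
$D$ is 0 exactly when every host carries the same count and approaches 1 as
the population concentrates on one host. It equals $\tfrac{N}{N+1}$ times
the Gini coefficient, which supplies an independent brute-force oracle (the
pairwise mean-absolute-difference form) against which the implementation is
tested exhaustively on all count vectors of length ≤ 5 with totals ≤ 12,
together with the Pigou–Dalton transfer property (moving one parasite from
a poorer to a strictly richer host strictly increases $D$).

### Goodness of fit

`gof_negbin()` compares observed count-class frequencies ($0, 1, 2, \dots$
plus one open tail class) with those expected under the fitted negative
binomial. Because expected frequencies in the sparse upper tail are tiny,
adjacent classes are pooled **from the tail inward** until every expected
frequency reaches `min_expected` (default 1.0; configurable because no
universal pooling convention exists). Degrees of freedom are
$\text{classes} - 3$: one for the constraint that frequencies sum to $N$,
two for the estimated parameters. If pooling cannot achieve the threshold
with at least 4 classes (df ≥ 1), an error is raised instead of a
meaningless test — with 30 hosts and strong aggregation this happens
already at moderate thresholds, which is why small-sample χ² values for
such censuses are essentially convention-dependent. The test's actual
type-I error under the fitted family (parameters re-estimated each
replicate) is checked by simulation: 200 replicate censuses of 1000 hosts
at $\mu = 15.6$, $k = 0.12$ give a rejection rate near the nominal 0.05.
With ungrouped ML estimates the statistic is only asymptotically χ²
(between $\chi^2_{c-3}$ and $\chi^2_{c-1}$); with the dozens of classes
these censuses produce, the difference is negligible.

## 2. Life-table demography

### The stage schedule

`stage_schedule()` bundles everything the demography needs, with defaults
calibrated to in vitro rearing of the hoopoe louse at 35 °C on a feather
diet: egg incubation 5.25 ± 0.97 d (range 4–7), nymphal instars
5.08 ± 0.85, 5.54 ± 0.84 and 6.04 ± 1.89 d, adult female lifespan
15.0 ± 6.28 d (2–24), adult male 10.96 ± 3.92 d (1–21), 0.35 eggs per
female per day, and a female egg fraction of $1.3/2.3 \approx 0.565$ taken
from the adult sex ratio (1 male : 1.3 females), assuming eggs are laid in
the adult ratio. Stage survival defaults to 1 for every immature stage:
rearing was protected (no host preening or predation), and no immature
mortality rates were reported; field attrition can be supplied per stage.
The reported lifetime fecundity of 6.1 eggs per female is carried as a
diagnostic only — it is not jointly consistent with
0.35 eggs/day × 15.0 days = 5.25, and the per-day rate is treated as
primary throughout.

### Life-table construction

`build_life_table()` produces a deterministic expected-cohort table on a
1-day age grid, age 0 being egg deposition; $m_x$ is credited at the end of
each adult day. The construction makes three explicit assumptions, each
configurable:

1. **Stage transitions** happen at the cumulative mean stage durations
   rounded to whole days (5, 10, 16, 22 for the default calibration, so
   adults emerge on day 22).
2. **Immature survivorship** steps down by the stage's survival probability
   at each transition.
3. **Adult survivorship** declines following the survival function of the
   schedule's truncated-normal adult-female lifespan distribution,
   evaluated at day midpoints: the fraction of emerged adults alive through
   adult day $j$ is $S(j + 0.5)$. The midpoint convention makes the summed
   adult survivorship equal the distribution's expected lifespan exactly,
   so a rectangular schedule (SD 0, lifespan $L$, daily fecundity $m$)
   yields $R_0 = L\,m$ with no half-day artefact. A linear decline hitting
   zero at twice the mean lifespan is available as
   `adult_survivorship = "linear"`; the distribution-based default was
   chosen because it uses information the schedule already carries (SD and
   range, not just the mean) and because the empirical life table of a
   simulated cohort converges to it as the cohort grows — under the linear
   decline the two would disagree even in the deterministic limit.

Fecundity is constant over adulthood,
$m_x = \text{eggs/female/day} \times \text{female fraction}$ (female eggs
per female per day), zero before emergence. The life table is female-based,
as is standard: $l_x$ tracks a female cohort, and males enter only through
the egg sex ratio.

### Demographic parameters

With the table in hand: $R_0 = \sum_x l_x m_x$ (`net_reproductive_rate`);
the intrinsic rate of natural increase $r_m$ solves the discrete
Euler–Lotka equation $\sum_x e^{-r x} l_x m_x = 1$ (`solve_rm`); generation
time $T = \ln R_0 / r_m$; doubling time $DT = \ln 2 / r_m$; finite rate
$\lambda = e^{r_m}$. All logarithms are natural. By construction
$e^{r_m T} = R_0$, $r_m > 0 \iff R_0 > 1$, and $DT < T$ exactly when
$R_0 > 2$.

The left-hand side of the Euler–Lotka equation is strictly decreasing in
$r$ whenever reproduction occurs at a positive age, so the real root is
unique. The solver brackets it starting from $[-2, 2]$ per day (far wider
than any arthropod growth rate), expands geometrically if needed, applies
Brent's method (`stats::uniroot`) and polishes with Newton steps until the
residual is below `tol` (default $10^{-10}$). A table whose entire
reproduction sits at a single age $a$ is solved in closed form,
$r_m = \ln(R_0)/a$; reproduction entirely at age 0 is rejected as
degenerate. At `rm = 0` exactly (replacement-level cohort), $T$ and $DT$
are undefined and error; the limit of $T$ is the cohort's mean age of
reproduction.

For the default calibration the package computes $R_0 \approx 2.84$ female
eggs per female, $r_m \approx 0.0358$ per day, $T \approx 29$ days and
$DT \approx 19.3$ days. Note that $R_0$, and hence $T$, depends strongly on
the assumed immature survival (here 1) and on the egg sex ratio, neither of
which was measured in the field; $r_m$ and $DT$ are less sensitive because
aggressive discounting concentrates the Euler–Lotka sum on the earliest
reproductive days. The package never forces agreement between $DT$ and
$\ln 2 / r_m$ computed from externally supplied round-valued rates: the
formula used is always $DT = \ln 2 / r_m$ with full-precision $r_m$.

## 3. Synthetic data

Three seeded generators stand in for the study's raw records; all are pure
functions of (parameters, seed), so identical calls are bit-identical.

* `simulate_host_counts()` draws censuses by the gamma-mixed Poisson
  construction (gamma shape $k$, mean $\mu$, then Poisson), which is the
  mechanistic definition of negative-binomial aggregation: hosts differ in
  exposure/susceptibility, and counts are Poisson around each host's rate.
  Moments converge to $\mu$ and $\mu(1 + \mu/k)$, and very large $k$
  recovers the Poisson limit — both tested at $n = 10^5$.
* `fixture_census()` produces a 30-host vector with exactly 12 infested
  hosts, positive counts in $[7, 83]$ and total 468, by clamped
  negative-binomial draws followed by unit-step adjustment in a seeded
  random host order until the total is exact. Every seed therefore yields
  prevalence 40%, mean intensity 39.0 and abundance 15.6. It is a
  constrained fixture honouring published summary statistics, **not** a
  reconstruction of the unpublished bird-by-bird census: quantities beyond
  the constraints (variance, $k$, $D$, χ²) vary across seeds and are not
  claims about the real data.
* `simulate_rearing_cohort()` draws, per individual: sex (Bernoulli at the
  female fraction), stage durations (normal truncated to the stage's
  range — chosen over a discretised gamma because the schedule's
  mean/SD/range parameters map onto it transparently), survival of each
  stage (death is placed at the would-be molt, matching the analytic
  convention of applying survival at stage completion), a sex-specific
  truncated-normal adult lifespan, and for surviving females a Poisson egg
  count with mean rate × lifespan. `cohort_to_life_table()` collapses the
  female subcohort into an empirical $(x, l_x, m_x)$ table after rounding
  event ages to the day grid, spreading each female's eggs uniformly over
  her adult days and scaling by the female egg fraction.

The generators emulate aggregation, stage-structured development and
censuses of realistic size. They do **not** emulate host-to-host
transmission, seasonal forcing, density dependence, host mortality, or
measurement error in delousing — so passing tests demonstrate internal
consistency of estimator and solver behaviour under the stated model, not
robustness to those field complications.

## 4. Numerical choices and edge cases

* Count classes and pooled labels are plain ASCII strings (`"0"`, `"1"`,
  `">=3"`), stable across runs.
* The truncated-normal sampler uses the inverse-CDF construction on
  `pnorm`/`qnorm`; SD = 0 is allowed and collapses to the mean (which must
  lie inside the range), and an empty truncation interval errors.
* Empirical survivorship treats entering the cohort as being alive at age
  0, so $l_0 = 1$ holds for any cohort.
* Reports isolate the timestamp in a single `meta` field; everything else
  is reproducible byte-for-byte, and JSON numbers are serialized at full
  precision with a separate rounded display block.
* Problem sizes used by the test-suite simulations — $10^5$ draws for
  moment convergence, 50 seeds × $n = 500$ for estimator recovery, 200
  replicates × $n = 1000$ for χ² calibration, $10^4$ individuals for the
  cohort/analytic cross-check, a $10^{-5}$-step grid scan for the
  Euler–Lotka oracle — were chosen as the smallest sizes at which the
  Monte-Carlo noise is comfortably below the tolerance being asserted.

## 5. Known limitations

* The χ² statistic for small, strongly aggregated censuses depends heavily
  on the pooling convention; published values without a stated convention
  cannot be reproduced, only the test's calibration can be verified.
* The expected-cohort life table is deterministic; stochastic demography
  (variance of $r_m$, stable age distribution, reproductive value) is out
  of scope.
* The moment and ML estimators of $k$ can differ substantially on small
  censuses (both are reported); neither is bias-corrected for $n \sim 30$.
* Fitting a stage schedule to censored rearing observations is not
  provided; the schedule is taken as given.
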