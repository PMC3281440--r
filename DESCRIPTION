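Package: lousepop
Title: Aggregation Statistics and Life-Table Demography for Ectoparasite
    Populations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of ectoparasite (chewing louse)
    populations in two parts. Host-level aggregation analysis of parasite
    counts: prevalence, mean intensity, sample mean abundance, the
    negative-binomial exponent k (moment and maximum-likelihood
    estimators), the index of discrepancy D, and a chi-squared
    goodness-of-fit test against the negative binomial with tail-inward
    class pooling. Cohort demography from in vitro rearing schedules:
    life-table construction from stage-duration and fecundity parameters,
    the net reproductive rate R0, the Euler-Lotka intrinsic rate of
    natural increase rm, generation time and population doubling time.
    Includes seeded generators for synthetic host censuses and rearing
    cohorts, delimited-text and YAML/JSON readers and writers, and a
    reproducible JSON reporting pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
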