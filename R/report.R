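#' Full aggregation analysis of a host census
#'
#' Runs the complete aggregation workflow on one vector of per-host
#' counts: descriptive summary, index of discrepancy, negative-binomial
#' exponent by both the moment and the maximum-likelihood estimator (the
#' ML value is the headline), and the chi-squared goodness of fit against
#' the ML fit. Steps that are undefined for the data at hand (no
#' overdispersion for the moment estimator; too few poolable classes for
#' the chi-squared test) are reported as notes rather than aborting the
#' analysis.
#'
#' @param counts Numeric vector of non-negative integer counts per host.
#' @param min_expected Pooling threshold passed to [gof_negbin()].
#' @return A list with elements `summary` ([summarize_counts()]),
#'   `discrepancy_D`, `negbin` (sub-lists `mle` and `moments`, each either
#'   a fit or a `note`), and `gof` (a [gof_negbin()] result or a `note`).
#' @export
analyze_aggregation <- function(counts, min_expected = 1) {
  x <- check_counts(counts)
  smry <- summarize_counts(x)
  D <- tryCatch(index_of_discrepancy(x),
                error = function(e) NA_real_)
  mle <- tryCatch(fit_negbin_mle(x),
                  error = function(e) list(note = conditionMessage(e)),
                  warning = function(w) {
                    f <- suppressWarnings(fit_negbin_mle(x))
                    f
                  })
  mom <- tryCatch(fit_negbin_moments(x),
                  error = function(e) list(note = conditionMessage(e)))
  gof <- if (inherits(mle, "negbin_fit") && isTRUE(mle$converged)) {
    tryCatch(gof_negbin(x, mle, min_expected = min_expected),
             error = function(e) list(note = conditionMessage(e)))
  } else list(note = "no converged ML fit available for goodness of fit")
  list(summary = smry, discrepancy_D = D,
       negbin = list(mle = mle, moments = mom), gof = gof)
}

fit_block <- function(fit) {
  if (inherits(fit, "negbin_fit"))
    list(k = fit$k, mean = fit$mean, method = fit$method,
         loglik = fit$loglik, converged = fit$converged)
  else fit  # note
}

gof_block <- function(gof) {
  if (inherits(gof, "gof_result"))
    list(chi2 = gof$chi2, df = gof$df, p_value = gof$p_value,
         classes = gof$classes)
  else gof  # note
}

#' Run the full reporting pipeline
#'
#' Reads a host census (CSV/TSV) and a stage schedule (YAML/JSON), runs
#' the aggregation and demography analyses, and assembles a single
#' reproducible report: a `meta` block (package version, seed, input MD5
#' digests, configuration echo, and the one timestamp field), an
#' `aggregation` block, a `demography` block, and a `display` block with
#' rounded headline numbers. All numeric fields are serialized at full
#' precision. The report is validated against the packaged schema before
#' any file is written, and the JSON is written atomically (temp file then
#' rename), so a failing run leaves no partial output.
#'
#' @param counts_path Path to the host census (see [read_host_counts()]).
#' @param schedule_path Path to the stage schedule
#'   (see [read_stage_schedule()]).
#' @param out Optional path for the JSON report.
#' @param seed Optional integer seed, echoed into the report for
#'   provenance (the pipeline itself is deterministic).
#' @param min_expected Chi-squared pooling threshold.
#' @param tol Euler-Lotka residual tolerance.
#' @param max_age Oldest age in the constructed life table (days);
#'   `NULL` for the schedule-derived default.
#' @return The report, as a nested list, invisibly.
#' @examples
#' counts_file <- tempfile(fileext = ".csv")
#' write_host_counts(fixture_census(seed = 1), counts_file)
#' sched_file <- tempfile(fileext = ".yaml")
#' write_stage_schedule(stage_schedule(), sched_file)
#' rep <- run_full_report(counts_file, sched_file, seed = 1)
#' rep$aggregation$summary$prevalence
#' @export
run_full_report <- function(counts_path, schedule_path, out = NULL,
                            seed = NULL, min_expected = 1, tol = 1e-10,
                            max_age = NULL) {
  for (p in c(counts_path, schedule_path))
    if (!file.exists(p))
      stop("input file not found: ", p, call. = FALSE)

  counts <- read_host_counts(counts_path)
  schedule <- read_stage_schedule(schedule_path)

  agg <- analyze_aggregation(counts, min_expected = min_expected)
  lt <- build_life_table(schedule, max_age = max_age)
  dem <- demography(lt, tol = tol)

  report <- list(
    meta = list(
      tool = "lousepop",
      version = as.character(utils::packageVersion("lousepop")),
      seed = if (is.null(seed)) NA else as.integer(seed),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      inputs = list(
        counts = list(path = counts_path,
                      md5 = unname(tools::md5sum(counts_path))),
        schedule = list(path = schedule_path,
                        md5 = unname(tools::md5sum(schedule_path)))
      ),
      config = list(min_expected = min_expected, tol = tol,
                    max_age = if (is.null(max_age)) NA else max_age)
    ),
    aggregation = list(
      summary = unclass(agg$summary),
      discrepancy_D = agg$discrepancy_D,
      negbin = list(mle = fit_block(agg$negbin$mle),
                    moments = fit_block(agg$negbin$moments)),
      gof = gof_block(agg$gof)
    ),
    demography = list(
      rm = dem$rm, R0 = dem$R0, T = dem$T, DT = dem$DT, lam = dem$lam,
      life_table_ages = nrow(lt)
    ),
    display = list(
      prevalence_pct = round(100 * agg$summary$prevalence, 1),
      mean_intensity = round(agg$summary$mean_intensity, 1),
      mean_abundance = round(agg$summary$mean_abundance, 1),
      variance_to_mean = round(agg$summary$variance_to_mean, 2),
      discrepancy_D = round(agg$discrepancy_D, 3),
      k_mle = if (inherits(agg$negbin$mle, "negbin_fit"))
        round(agg$negbin$mle$k, 3) else NA,
      rm = round(dem$rm, 4), R0 = round(dem$R0, 3),
      T = round(dem$T, 2), DT = round(dem$DT, 2)
    )
  )
  validate_report(report)
  if (!is.null(out)) {
    tmp <- paste0(out, ".tmp")
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
    file.rename(tmp, out)
  }
  invisible(report)
}

#' Validate a report against the packaged JSON schema
#'
#' Structural validation: every field required by the versioned schema
#' shipped at `inst/schema/report-schema-v1.json` must be present with a
#' compatible type. Nested objects are checked recursively.
#'
#' @param report Report list, as returned by [run_full_report()].
#' @param schema_path Path to the schema; defaults to the packaged one.
#' @return `TRUE` invisibly, or an error listing every violation.
#' @export
validate_report <- function(report,
                            schema_path = system.file("schema",
                              "report-schema-v1.json",
                              package = "lousepop")) {
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  problems <- character(0)
  check_node <- function(node, node_schema, where) {
    for (key in names(node_schema$required)) {
      sub <- node_schema$required[[key]]
      here <- paste0(where, "$", key)
      if (!key %in% names(node)) {
        problems <<- c(problems, paste0("missing field ", here))
        next
      }
      val <- node[[key]]
      type <- if (is.character(sub)) sub else sub$type
      ok <- switch(type,
        number = is.numeric(val) || all(is.na(val)),
        string = is.character(val) || all(is.na(val)),
        logical = is.logical(val),
        object = is.list(val),
        any = TRUE,
        FALSE)
      if (!ok)
        problems <<- c(problems,
                       paste0(here, " has type ", class(val)[1],
                              ", expected ", type))
      if (!is.character(sub) && !is.null(sub$required) && is.list(val))
        check_node(val, sub, here)
    }
  }
  check_node(report, schema, "report")
  if (length(problems))
    stop("report does not conform to schema v", schema$version, ":\n",
         paste0("  - ", problems, collapse = "\n"), call. = FALSE)
  invisible(TRUE)
}
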