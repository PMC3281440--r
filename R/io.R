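#' Read per-host parasite counts from delimited text
#'
#' Expects a header row and columns `host_id` and `count`; comma-separated
#' by default, tab-separated for `.tsv` files. Counts must parse as
#' non-negative integers; the first offending row and column are named in
#' the error.
#'
#' @param path Path to a CSV/TSV file.
#' @return Named integer vector of counts (names are host ids).
#' @export
read_host_counts <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character", strip.white = TRUE)
  for (col in c("host_id", "count"))
    if (!col %in% names(df))
      stop("missing required column '", col, "' in ", path, call. = FALSE)
  counts <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad))
    stop(sprintf("malformed value in %s: row %d, column 'count' (%s) %s",
                 path, bad[1], df$count[bad[1]],
                 "is not a non-negative integer"), call. = FALSE)
  stats::setNames(as.integer(counts), df$host_id)
}

#' Write per-host parasite counts as CSV
#'
#' @param counts Named or unnamed integer vector of counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_host_counts <- function(counts, path) {
  x <- check_counts(counts)
  ids <- names(counts)
  if (is.null(ids)) ids <- sprintf("host%03d", seq_along(x))
  utils::write.csv(data.frame(host_id = ids, count = as.integer(x)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stage schedule from a YAML or JSON configuration file
#'
#' The file mirrors the [stage_schedule()] fields: a `stages` list of
#' `{name, mean, sd, min, max}` entries, `adult_female_lifespan` and
#' `adult_male_lifespan` maps with `mean/sd/min/max`, scalars
#' `eggs_per_female_day`, `lifetime_eggs_per_female`, `female_fraction`,
#' and a `stage_survival` map keyed by stage name. All validation problems
#' are reported together.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [stage_schedule()].
#' @export
read_stage_schedule <- function(path) {
  if (!file.exists(path))
    stop("schedule file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  need <- c("stages", "adult_female_lifespan", "adult_male_lifespan",
            "eggs_per_female_day", "female_fraction", "stage_survival")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("schedule file ", path, " is missing keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  stages <- do.call(rbind, lapply(raw$stages, function(s)
    data.frame(stage = s$name, mean = s$mean, sd = s$sd,
               min = s$min, max = s$max, stringsAsFactors = FALSE)))
  span <- function(v) c(mean = v$mean, sd = v$sd, min = v$min, max = v$max)
  stage_schedule(
    stages = stages,
    adult_female = span(raw$adult_female_lifespan),
    adult_male = span(raw$adult_male_lifespan),
    eggs_per_female_day = raw$eggs_per_female_day,
    lifetime_eggs_per_female = if (!is.null(raw$lifetime_eggs_per_female))
      raw$lifetime_eggs_per_female else 0,
    female_fraction = raw$female_fraction,
    stage_survival = unlist(raw$stage_survival)
  )
}

#' Write a stage schedule to YAML or JSON
#'
#' @param schedule A [stage_schedule()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_stage_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "stage_schedule"))
  spanl <- function(v) list(mean = unname(v[["mean"]]), sd = unname(v[["sd"]]),
                            min = unname(v[["min"]]), max = unname(v[["max"]]))
  doc <- list(
    stages = lapply(seq_len(nrow(schedule$stages)), function(i)
      list(name = schedule$stages$stage[i],
           mean = schedule$stages$mean[i], sd = schedule$stages$sd[i],
           min = schedule$stages$min[i], max = schedule$stages$max[i])),
    adult_female_lifespan = spanl(schedule$adult_female),
    adult_male_lifespan = spanl(schedule$adult_male),
    eggs_per_female_day = schedule$eggs_per_female_day,
    lifetime_eggs_per_female = schedule$lifetime_eggs_per_female,
    female_fraction = schedule$female_fraction,
    stage_survival = as.list(schedule$stage_survival)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read and write life tables as 3-column CSV
#'
#' The on-disk format is a plain CSV with header `x,lx,mx`.
#'
#' @param path File path.
#' @return `read_life_table()` returns a [life_table()];
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path))
    stop("life-table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  for (col in c("x", "lx", "mx"))
    if (!col %in% names(df))
      stop("missing required column '", col, "' in ", path, call. = FALSE)
  life_table(df$x, df$lx, df$mx)
}

#' @rdname read_life_table
#' @param lt A [life_table()].
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt)[, c("x", "lx", "mx")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
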