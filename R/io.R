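# Artifact (de)serialization: session logs as JSON Lines (one event per
# line, preceded by a header line), score/validity reports as JSON, cohort
# tables as CSV.

.pkg_version <- function() {
  as.character(utils::packageVersion("dkasim"))
}

#' Write a session log as JSON Lines
#'
#' The first line is a header object (schema version, scenario id, scored
#' flag, tool version); each subsequent line is one event. Numeric fields are
#' written at full precision so a write-read round trip is the identity.
#'
#' @param log a `dka_session_log`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "dka_session_log"))
  header <- list(type = "header", schema_version = log$schema_version,
                 scenario_id = log$scenario_id, scored = log$scored,
                 tool_version = .pkg_version())
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
    vapply(log$events, function(e)
      as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)),
      character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a session log written by [write_session_log()]
#' @param path path to a JSON Lines session log
#' @return a `dka_session_log`
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty session log file", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  if (!identical(header$type, "header"))
    stop("session log must start with a header line", call. = FALSE)
  events <- lapply(lines[-1], function(l)
    .canonical_event(jsonlite::fromJSON(l, simplifyVector = FALSE)))
  structure(list(scenario_id = header$scenario_id,
                 schema_version = as.integer(header$schema_version),
                 scored = isTRUE(header$scored), events = events),
            class = "dka_session_log")
}

# normalize a deserialized event so replayed logs compare identical to live
# ones (times integer, payload a plain named list of scalars)
.canonical_event <- function(e) {
  e$time <- as.integer(e$time)
  if (!is.null(e$minutes)) e$minutes <- as.numeric(e$minutes)
  if (!is.null(e$payload)) e$payload <- lapply(e$payload, function(v) v)
  e
}

#' Write a report (score report, summary report or validity report) as JSON
#' @param x the report object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(.report_as_list(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

.report_as_list <- function(x) {
  out <- unclass(x)
  out$tool_version <- .pkg_version()
  out
}

#' Write a cohort table as CSV
#' @param cohort a `dka_cohort` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects the column dictionary produced by [generate_cohort()]:
#' `participant_id`, `group` (MS1/MS3/PGY2/Staff), `age_group`, `gender`,
#' `english_first_language`, `weeks_on_gim`, `comfort`,
#' `n_dka_treated_band`, `total_score`, `percent_score`, `duration_s`.
#'
#' @param path path to a cohort CSV
#' @return a `dka_cohort` data.frame
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_cohort(df)
}

.validate_cohort <- function(df) {
  needed <- c("participant_id", "group", "total_score", "percent_score",
              "duration_s")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$group), c("MS1", "MS3", "PGY2", "Staff"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(df$total_score < 18 | df$total_score > 54))
    stop("total_score outside the 18-54 range", call. = FALSE)
  df$group <- factor(df$group, levels = c("MS1", "MS3", "PGY2", "Staff"))
  class(df) <- c("dka_cohort", "data.frame")
  df
}

# stable fingerprint of a cohort table, for reproducibility stamps
.cohort_hash <- function(df) {
  f <- tempfile()
  on.exit(unlink(f))
  utils::write.csv(df[order(df$participant_id), ], f, row.names = FALSE)
  unname(tools::md5sum(f))
}
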