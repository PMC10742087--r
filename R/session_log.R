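LOG_SCHEMA_VERSION <- 1L

#' Construct a validated session log entry
#'
#' One record of a completed (or early-ended) session: day, start timestamp,
#' how much of the scheduled duration was completed, and the baseline tremor
#' frequency the session ran at.
#'
#' @param day Protocol day.
#' @param started_at Session start timestamp, ISO-8601 string with timezone
#'   offset (e.g. `"2026-09-19T14:30:00-0500"`).
#' @param completed_duration Seconds actually completed,
#'   `0 <= completed_duration <= scheduled_duration`.
#' @param scheduled_duration Scheduled session length in seconds.
#' @param baseline_frequency Baseline tremor frequency in Hz.
#' @param baseline_significant Whether the baseline came from a significant
#'   tremor peak (`FALSE` = fallback frequency was used).
#' @return A `session_log_entry` list; `ended_early` is derived as
#'   `completed_duration < scheduled_duration`.
#' @export
session_log_entry <- function(day, started_at, completed_duration,
                              scheduled_duration, baseline_frequency,
                              baseline_significant) {
  if (length(day) != 1L || day != as.integer(day) || day < 1)
    stop("day must be a positive integer", call. = FALSE)
  if (!is.character(started_at) || length(started_at) != 1L ||
      !grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}", started_at))
    stop("started_at must be an ISO-8601 timestamp string", call. = FALSE)
  if (completed_duration < 0 || completed_duration > scheduled_duration)
    stop("completed_duration must lie in [0, scheduled_duration]", call. = FALSE)
  if (baseline_frequency <= 0)
    stop("baseline_frequency must be positive", call. = FALSE)
  structure(
    list(schema_version = LOG_SCHEMA_VERSION,
         day = as.integer(day),
         started_at = started_at,
         completed_duration = as.numeric(completed_duration),
         scheduled_duration = as.numeric(scheduled_duration),
         baseline_frequency = as.numeric(baseline_frequency),
         baseline_significant = isTRUE(baseline_significant),
         ended_early = completed_duration < scheduled_duration),
    class = "session_log_entry"
  )
}

#' Append a session log entry to a JSON-lines log file
#'
#' The log is append-only: one self-describing JSON record per line, UTF-8,
#' carrying a `schema_version` field. Created if absent.
#'
#' @param path Log file path.
#' @param entry A [session_log_entry()].
#' @return Invisibly, `path`.
#' @export
append_log_entry <- function(path, entry) {
  stopifnot(inherits(entry, "session_log_entry"))
  line <- jsonlite::toJSON(unclass(entry), auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(line, con)
  invisible(path)
}

#' Read a session log file
#'
#' Parses every line back into a [session_log_entry()]; a malformed or
#' truncated line, or a record written under a different schema version, is
#' reported with its line number. A missing file reads as an empty log.
#'
#' @param path Log file path.
#' @return List of `session_log_entry` objects in file (append) order.
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  entries <- vector("list", length(lines))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) NULL)
    if (is.null(rec) || !is.list(rec))
      stop("malformed log record at line ", i, call. = FALSE)
    if (is.null(rec$schema_version) ||
        rec$schema_version != LOG_SCHEMA_VERSION)
      stop("schema version mismatch at line ", i, call. = FALSE)
    entries[[i]] <- tryCatch(
      session_log_entry(rec$day, rec$started_at, rec$completed_duration,
                        rec$scheduled_duration, rec$baseline_frequency,
                        rec$baseline_significant),
      error = function(e)
        stop("malformed log record at line ", i, ": ", conditionMessage(e),
             call. = FALSE))
    keep[i] <- TRUE
  }
  entries[keep]
}

#' Completion (adherence) metrics from a session log
#'
#' Adherence is duration-weighted: the completed seconds divided by the
#' scheduled seconds over a day set. Days of the protocol with no log entry
#' count as zero completed seconds over their full scheduled duration, so
#' skipping a session lowers the fraction. The at-home fraction covers days
#' 2 onward only (day 1 is the supervised session).
#'
#' @param entries List of [session_log_entry()] objects, at most one per day.
#' @param cfg A [protocol_config()] supplying the day schedule.
#' @return List with `per_day` (data frame: `day`, `completed_duration`,
#'   `scheduled_duration`, `fraction`), `at_home_fraction`,
#'   `overall_fraction`.
#' @export
completion_metrics <- function(entries, cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  days <- vapply(entries, `[[`, integer(1), "day")
  if (anyDuplicated(days))
    stop("duplicate day entries: ", paste(unique(days[duplicated(days)]),
         collapse = ", "), " (one session per day)", call. = FALSE)
  if (length(days) > 0L && any(days > cfg$n_days))
    stop("entry day outside the ", cfg$n_days, "-day protocol", call. = FALSE)
  all_days <- seq_len(cfg$n_days)
  completed <- numeric(cfg$n_days)
  scheduled <- vapply(all_days, scheduled_duration, numeric(1), cfg = cfg)
  for (e in entries) {
    completed[e$day] <- e$completed_duration
    scheduled[e$day] <- e$scheduled_duration
  }
  per_day <- data.frame(day = all_days,
                        completed_duration = completed,
                        scheduled_duration = scheduled,
                        fraction = completed / scheduled)
  home <- all_days > 1L
  list(per_day = per_day,
       at_home_fraction = if (any(home)) sum(completed[home]) / sum(scheduled[home]) else 0,
       overall_fraction = sum(completed) / sum(scheduled))
}
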