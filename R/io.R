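# Readers and writers for the observation-log CSV schemas.
#
# All files are UTF-8 CSV with a fixed header and "." decimal separator.
# Times are seconds from the start of the focal session; seasons are opaque
# labels, never parsed as dates. Readers validate and reject malformed input
# rather than coercing it; every writer produces files its reader accepts.

EVENT_BEHAVIORS <- c("approach", "displacement", "groom", "aggression")
SCAN_STATES <- c("contact", "proximity", "co-provisioning")

EVENT_COLS <- c("season", "session_id", "focal_id", "actor_id",
                "recipient_id", "behavior", "start", "end")
SCAN_COLS <- c("season", "session_id", "focal_id", "partner_id",
               "state", "scan_time")
ROSTER_COLS <- c("individual_id", "age", "matriline_id", "mother_id")
SESSION_COLS <- c("season", "session_id", "focal_id", "duration_min")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    schema_error("%s: missing column(s) %s", what,
                 paste(missing, collapse = ", "))
  df[cols]
}

#' Validate a focal continuous event log
#'
#' An event log holds timestamped directed behavioral events from focal
#' follows: one row per approach, displacement, grooming segment or
#' aggressive act, with actor, recipient, behavior code and times in seconds
#' from the start of the focal session. Grooming rows additionally carry an
#' `end` time.
#'
#' @param events data.frame with columns `season`, `session_id`, `focal_id`,
#'   `actor_id`, `recipient_id`, `behavior`, `start`, `end`.
#' @return the validated data.frame (columns in canonical order), invisibly
#'   usable as an event log.
#' @export
validate_event_log <- function(events) {
  events <- check_columns(as.data.frame(events), EVENT_COLS, "event log")
  for (col in c("season", "session_id", "focal_id", "actor_id",
                "recipient_id", "behavior"))
    events[[col]] <- as.character(events[[col]])
  events$start <- suppressWarnings(as.numeric(events$start))
  events$end <- suppressWarnings(as.numeric(events$end))
  bad <- which(!events$behavior %in% EVENT_BEHAVIORS)
  if (length(bad))
    schema_error("event log row %d: unknown behavior '%s'",
                 bad[1], events$behavior[bad[1]])
  bad <- which(events$actor_id == events$recipient_id)
  if (length(bad))
    schema_error("event log row %d: actor equals recipient ('%s')",
                 bad[1], events$actor_id[bad[1]])
  bad <- which(events$behavior == "groom" & !is.finite(events$end))
  if (length(bad))
    schema_error("event log row %d: groom event missing end time", bad[1])
  bad <- which(is.finite(events$end) & events$end < events$start)
  if (length(bad))
    schema_error("event log row %d: end (%g) before start (%g)",
                 bad[1], events$end[bad[1]], events$start[bad[1]])
  bad <- which(!is.finite(events$start))
  if (length(bad))
    schema_error("event log row %d: missing start time", bad[1])
  events
}

#' Validate an instantaneous scan log
#'
#' A scan log holds one row per scan sample in which the focal individual was
#' in a recorded dyadic state (body contact, proximity within arm's reach, or
#' co-provisioning at a shared food source) with a partner. Scans in which
#' the focal had no partner state are simply absent.
#'
#' @param scans data.frame with columns `season`, `session_id`, `focal_id`,
#'   `partner_id`, `state`, `scan_time`.
#' @return the validated data.frame.
#' @export
validate_scan_log <- function(scans) {
  scans <- check_columns(as.data.frame(scans), SCAN_COLS, "scan log")
  for (col in c("season", "session_id", "focal_id", "partner_id", "state"))
    scans[[col]] <- as.character(scans[[col]])
  scans$scan_time <- suppressWarnings(as.numeric(scans$scan_time))
  bad <- which(!scans$state %in% SCAN_STATES)
  if (length(bad))
    schema_error("scan log row %d: unknown state '%s'",
                 bad[1], scans$state[bad[1]])
  bad <- which(scans$focal_id == scans$partner_id)
  if (length(bad))
    schema_error("scan log row %d: focal equals partner ('%s')",
                 bad[1], scans$focal_id[bad[1]])
  bad <- which(!is.finite(scans$scan_time))
  if (length(bad))
    schema_error("scan log row %d: missing scan_time", bad[1])
  scans
}

#' Validate an individual roster
#'
#' @param roster data.frame with columns `individual_id`, `age` (years),
#'   `matriline_id`, `mother_id` (empty/NA for matriline founders).
#' @return the validated data.frame.
#' @export
validate_roster <- function(roster) {
  roster <- check_columns(as.data.frame(roster), ROSTER_COLS, "roster")
  roster$individual_id <- as.character(roster$individual_id)
  roster$matriline_id <- as.character(roster$matriline_id)
  roster$mother_id <- as.character(roster$mother_id)
  roster$mother_id[!is.na(roster$mother_id) & roster$mother_id == ""] <-
    NA_character_
  roster$age <- suppressWarnings(as.numeric(roster$age))
  dup <- roster$individual_id[duplicated(roster$individual_id)]
  if (length(dup))
    schema_error("roster: duplicate individual_id '%s'", dup[1])
  bad <- which(!is.finite(roster$age) | roster$age < 0)
  if (length(bad))
    schema_error("roster row %d: age must be a non-negative number", bad[1])
  roster
}

validate_session_table <- function(sessions) {
  sessions <- check_columns(as.data.frame(sessions), SESSION_COLS,
                            "session table")
  for (col in c("season", "session_id", "focal_id"))
    sessions[[col]] <- as.character(sessions[[col]])
  sessions$duration_min <- suppressWarnings(as.numeric(sessions$duration_min))
  bad <- which(!is.finite(sessions$duration_min) | sessions$duration_min <= 0)
  if (length(bad))
    schema_error("session table row %d: duration_min must be > 0", bad[1])
  sessions
}

read_log <- function(path, validator, what) {
  if (!file.exists(path)) schema_error("%s file not found: %s", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  validator(df)
}

#' Read / write observation-log CSV files
#'
#' @param path file path.
#' @param events,scans,roster,sessions validated (or validatable) data.frames.
#' @return readers return the validated data.frame; writers return the path
#'   invisibly.
#' @name log_io
#' @export
read_event_log <- function(path) read_log(path, validate_event_log, "event log")

#' @rdname log_io
#' @export
write_event_log <- function(events, path) {
  events <- validate_event_log(events)
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname log_io
#' @export
read_scan_log <- function(path) read_log(path, validate_scan_log, "scan log")

#' @rdname log_io
#' @export
write_scan_log <- function(scans, path) {
  scans <- validate_scan_log(scans)
  utils::write.csv(scans, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname log_io
#' @export
read_roster <- function(path) read_log(path, validate_roster, "roster")

#' @rdname log_io
#' @export
write_roster <- function(roster, path) {
  roster <- validate_roster(roster)
  utils::write.csv(roster, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname log_io
#' @export
read_session_table <- function(path)
  read_log(path, validate_session_table, "session table")

#' @rdname log_io
#' @export
write_session_table <- function(sessions, path) {
  sessions <- validate_session_table(sessions)
  utils::write.csv(sessions, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a square sociometric matrix
#'
#' A sociometric matrix is a square actor-by-recipient matrix of non-negative
#' counts or minutes, with individual ids as both row and column names and an
#' undefined (stored-as-zero, never read) diagonal. The CSV layout has an id
#' header row and the same ids in the first column; id order is preserved
#' exactly as in the file.
#'
#' @param path file path.
#' @param m numeric matrix with identical row and column names.
#' @return `read_matrix()` returns the matrix; `write_matrix()` the path,
#'   invisibly.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) schema_error("matrix file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) schema_error("matrix file %s: no data columns", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    schema_error("matrix file %s: not square (%d rows, %d columns)",
                 path, nrow(m), ncol(m))
  if (!identical(ids, colnames(m)))
    schema_error("matrix file %s: row ids do not match column ids", path)
  if (anyNA(m) || any(m < 0))
    schema_error("matrix file %s: entries must be non-negative numbers", path)
  dimnames(m) <- list(ids, ids)
  m
}

#' @rdname read_matrix
#' @export
write_matrix <- function(m, path) {
  m <- check_sociometric(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_sociometric <- function(m, what = "sociometric matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    schema_error("%s must be a numeric matrix", what)
  if (nrow(m) != ncol(m))
    schema_error("%s must be square (got %d x %d)", what, nrow(m), ncol(m))
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    schema_error("%s must carry identical row and column ids", what)
  if (anyNA(m) || any(m < 0))
    schema_error("%s entries must be non-negative", what)
  m
}

#' Focal observation time per individual and season
#'
#' Sums focal-session durations per individual per season. Seasons are kept
#' separate, never pooled.
#'
#' @param sessions a session table (`season`, `session_id`, `focal_id`,
#'   `duration_min`).
#' @param roster optional roster; if supplied, every focal id must appear in
#'   it and individuals without sessions get 0 hours.
#' @return data.frame with columns `individual_id`, `season`, `hours`.
#' @export
observation_time <- function(sessions, roster = NULL) {
  sessions <- validate_session_table(sessions)
  if (!is.null(roster)) {
    roster <- validate_roster(roster)
    unknown <- setdiff(unique(sessions$focal_id), roster$individual_id)
    if (length(unknown))
      key_error("focal individual(s) absent from roster: %s",
                paste(unknown, collapse = ", "))
  }
  if (nrow(sessions) == 0) {
    out <- data.frame(individual_id = character(), season = character(),
                      hours = numeric())
  } else {
    agg <- stats::aggregate(duration_min ~ focal_id + season, data = sessions,
                            FUN = sum)
    out <- data.frame(individual_id = agg$focal_id, season = agg$season,
                      hours = agg$duration_min / 60)
  }
  if (!is.null(roster) && nrow(out) > 0) {
    full <- expand.grid(individual_id = roster$individual_id,
                        season = unique(sessions$season),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- merge(full, out, all.x = TRUE)
    out$hours[is.na(out$hours)] <- 0
  }
  out <- out[order(out$season, out$individual_id), ]
  rownames(out) <- NULL
  out
}

# hours lookup helper: named vector for one season
hours_vector <- function(obs_hours, season, ids) {
  h <- obs_hours[obs_hours$season == season, ]
  v <- stats::setNames(h$hours, h$individual_id)
  missing <- setdiff(ids, names(v))
  if (length(missing))
    key_error("no observation time for individual(s): %s",
              paste(missing, collapse = ", "))
  v[ids]
}
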