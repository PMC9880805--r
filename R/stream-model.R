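# Domain tables and their CSV round-trip.
#
# Every stream the system touches is a plain tibble with a fixed column
# contract, validated on read and on construction:
#   minute stream : participant_id, timestamp, steps, worn
#   symptoms      : participant_id, timestamp, <10 severity columns>
#   sleep         : participant_id, start, end
#   events        : participant_id, timestamp, threshold_used, responded,
#                   response_steps, feedback_sent
# Timestamps are minute-granular, timezone-naive local time (stored as UTC
# POSIXct); one row per participant-minute. Missing minutes are legal in a
# minute stream; their interpretation is decided downstream.

#' Construct and validate a minute-level step stream
#'
#' @param participant_id character.
#' @param timestamp POSIXct or ISO-8601 strings, minute resolution.
#' @param steps non-negative integer step counts.
#' @param worn logical wear flag.
#' @return Validated tibble sorted by (participant, timestamp).
#' @export
minute_stream <- function(participant_id, timestamp, steps, worn) {
  df <- tibble::tibble(
    participant_id = as.character(participant_id),
    timestamp = if (inherits(timestamp, "POSIXct")) floor_minute(timestamp) else parse_minute_ts(timestamp),
    steps = as.integer(steps),
    worn = as.logical(worn)
  )
  validate_minute_stream(df)
}

#' Validate a minute stream tibble
#'
#' Checks the column contract, non-negative steps, no missing fields, and
#' uniqueness of each participant-minute; returns the stream sorted by
#' (participant, timestamp).
#'
#' @param df tibble with columns participant_id, timestamp, steps, worn.
#' @return The validated, sorted tibble.
#' @export
validate_minute_stream <- function(df) {
  need <- c("participant_id", "timestamp", "steps", "worn")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) validation_error("minute stream missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(df$participant_id) || anyNA(df$timestamp)) {
    validation_error("minute stream has missing participant_id or timestamp (row %d)",
                     which(is.na(df$participant_id) | is.na(df$timestamp))[1])
  }
  if (anyNA(df$steps) || any(df$steps < 0)) {
    validation_error("steps must be non-negative integers (row %d)",
                     which(is.na(df$steps) | df$steps < 0)[1])
  }
  if (anyNA(df$worn)) validation_error("worn flag must be TRUE/FALSE (row %d)", which(is.na(df$worn))[1])
  df <- dplyr::arrange(df, .data$participant_id, .data$timestamp)
  key <- paste(df$participant_id, as.numeric(df$timestamp))
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    validation_error("duplicate participant-minute: %s @ %s",
                     df$participant_id[i], format_minute_ts(df$timestamp[i]))
  }
  df
}

#' Read a minute-level step stream CSV
#'
#' Expects header `participant_id,timestamp,steps,worn` with ISO-8601
#' minute timestamps. Rows are validated (non-negative steps, no duplicate
#' participant-minutes) and returned sorted by (participant, timestamp).
#'
#' @param path file path.
#' @return Validated minute-stream tibble.
#' @export
read_minute_stream <- function(path) {
  raw <- read_csv_checked(path, c("participant_id", "timestamp", "steps", "worn"),
                          readr::cols(participant_id = readr::col_character(),
                                      timestamp = readr::col_character(),
                                      steps = readr::col_integer(),
                                      worn = readr::col_logical()))
  minute_stream(raw$participant_id, raw$timestamp, raw$steps, raw$worn)
}

#' Write a minute stream CSV
#'
#' @param df validated minute stream.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_minute_stream <- function(df, path) {
  df <- validate_minute_stream(df)
  out <- dplyr::mutate(df, timestamp = format_minute_ts(.data$timestamp))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct and validate daily symptom reports
#'
#' One row per report: a timestamp and ten named severities, each an integer
#' in 0-10. Severity columns follow [SYMPTOM_DIMENSIONS].
#'
#' @param participant_id character.
#' @param timestamp POSIXct or ISO-8601 strings.
#' @param severities data frame or matrix with the ten severity columns.
#' @return Validated tibble sorted by (participant, timestamp).
#' @export
symptom_reports <- function(participant_id, timestamp, severities) {
  sev <- tibble::as_tibble(severities)
  df <- tibble::tibble(
    participant_id = as.character(participant_id),
    timestamp = if (inherits(timestamp, "POSIXct")) floor_minute(timestamp) else parse_minute_ts(timestamp)
  )
  df <- dplyr::bind_cols(df, sev)
  validate_symptom_reports(df)
}

#' Validate a symptom-report tibble
#' @param df tibble with participant_id, timestamp and the ten severity columns.
#' @return The validated, sorted tibble.
#' @export
validate_symptom_reports <- function(df) {
  miss <- setdiff(c("participant_id", "timestamp", SYMPTOM_DIMENSIONS), names(df))
  if (length(miss) > 0) validation_error("symptom reports missing column(s): %s", paste(miss, collapse = ", "))
  sev <- as.matrix(df[SYMPTOM_DIMENSIONS])
  if (anyNA(sev) || any(sev < 0) || any(sev > 10) || any(sev != floor(sev))) {
    bad <- which(rowSums(is.na(sev) | sev < 0 | sev > 10 | sev != floor(sev)) > 0)[1]
    validation_error("severities must be integers in [0, 10] (row %d)", bad)
  }
  df <- df[c("participant_id", "timestamp", SYMPTOM_DIMENSIONS)]
  dplyr::arrange(df, .data$participant_id, .data$timestamp)
}

#' Read a symptom-report CSV
#' @param path file path.
#' @return Validated symptom-report tibble.
#' @export
read_symptom_reports <- function(path) {
  raw <- read_csv_checked(path, c("participant_id", "timestamp", SYMPTOM_DIMENSIONS), NULL)
  symptom_reports(raw$participant_id, raw$timestamp, raw[SYMPTOM_DIMENSIONS])
}

#' Write a symptom-report CSV
#' @param df validated symptom reports.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_symptom_reports <- function(df, path) {
  df <- validate_symptom_reports(df)
  out <- dplyr::mutate(df, timestamp = format_minute_ts(.data$timestamp))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct and validate sleep episodes
#'
#' Device-detected sleep intervals `[start, end)`; episodes for a participant
#' must be non-overlapping and satisfy end > start.
#'
#' @param participant_id character.
#' @param start,end POSIXct or ISO-8601 strings.
#' @return Validated tibble sorted by (participant, start).
#' @export
sleep_episodes <- function(participant_id, start, end) {
  df <- tibble::tibble(
    participant_id = as.character(participant_id),
    start = if (inherits(start, "POSIXct")) floor_minute(start) else parse_minute_ts(start),
    end = if (inherits(end, "POSIXct")) floor_minute(end) else parse_minute_ts(end)
  )
  validate_sleep_episodes(df)
}

#' Validate sleep episodes
#' @param df tibble with participant_id, start, end.
#' @return The validated, sorted tibble.
#' @export
validate_sleep_episodes <- function(df) {
  miss <- setdiff(c("participant_id", "start", "end"), names(df))
  if (length(miss) > 0) validation_error("sleep episodes missing column(s): %s", paste(miss, collapse = ", "))
  if (any(df$end <= df$start)) {
    validation_error("sleep episode end must be after start (row %d)", which(df$end <= df$start)[1])
  }
  df <- dplyr::arrange(df, .data$participant_id, .data$start)
  if (nrow(df) > 1) {
    same <- df$participant_id[-1] == df$participant_id[-nrow(df)]
    overlap <- same & df$start[-1] < df$end[-nrow(df)]
    if (any(overlap)) {
      validation_error("overlapping sleep episodes for participant %s",
                       df$participant_id[-1][which(overlap)[1]])
    }
  }
  df
}

#' Read a sleep-episode CSV (participant_id,start,end)
#' @param path file path.
#' @return Validated sleep-episode tibble.
#' @export
read_sleep_episodes <- function(path) {
  raw <- read_csv_checked(path, c("participant_id", "start", "end"), NULL)
  sleep_episodes(raw$participant_id, raw$start, raw$end)
}

#' Write a sleep-episode CSV
#' @param df validated sleep episodes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sleep_episodes <- function(df, path) {
  df <- validate_sleep_episodes(df)
  out <- dplyr::mutate(df, start = format_minute_ts(.data$start), end = format_minute_ts(.data$end))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate prompt events
#'
#' Enforces the event invariants: `feedback_sent` implies `responded`, and
#' `responded` implies `response_steps >= response_step_goal`.
#'
#' @param df tibble with participant_id, timestamp, threshold_used,
#'   responded, response_steps, feedback_sent.
#' @param response_step_goal steps defining a response (default 30).
#' @return The validated tibble, sorted by (participant, timestamp).
#' @export
validate_events <- function(df, response_step_goal = 30L) {
  need <- c("participant_id", "timestamp", "threshold_used", "responded",
            "response_steps", "feedback_sent")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) validation_error("events missing column(s): %s", paste(miss, collapse = ", "))
  if (any(df$feedback_sent & !df$responded)) {
    validation_error("feedback_sent without responded (row %d)",
                     which(df$feedback_sent & !df$responded)[1])
  }
  if (any(df$responded & df$response_steps < response_step_goal)) {
    validation_error("responded with response_steps below the %d-step goal (row %d)",
                     response_step_goal, which(df$responded & df$response_steps < response_step_goal)[1])
  }
  if (any(df$response_steps < 0)) validation_error("response_steps must be >= 0")
  dplyr::arrange(df[need], .data$participant_id, .data$timestamp)
}

#' Write prompt events to CSV
#'
#' Stable column order `participant_id,timestamp,threshold_used,responded,
#' response_steps,feedback_sent`; a read-back equals the input.
#'
#' @param events validated event tibble (see [validate_events]).
#' @param path output path.
#' @param response_step_goal steps defining a response (invariant check).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, response_step_goal = 30L) {
  events <- validate_events(events, response_step_goal)
  out <- dplyr::mutate(events, timestamp = format_minute_ts(.data$timestamp))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a prompt-event CSV
#' @param path file path.
#' @param response_step_goal steps defining a response (invariant check).
#' @return Validated event tibble.
#' @export
read_events <- function(path, response_step_goal = 30L) {
  raw <- read_csv_checked(path, c("participant_id", "timestamp", "threshold_used",
                                  "responded", "response_steps", "feedback_sent"), NULL)
  raw$timestamp <- parse_minute_ts(raw$timestamp)
  raw$threshold_used <- as.integer(raw$threshold_used)
  raw$response_steps <- as.integer(raw$response_steps)
  raw$responded <- as.logical(raw$responded)
  raw$feedback_sent <- as.logical(raw$feedback_sent)
  validate_events(tibble::as_tibble(raw), response_step_goal)
}

#' Construct and validate wake windows
#'
#' A participant's waking interval between wake time and bedtime, the only
#' period in which prompts may be delivered. Windows are effective-dated;
#' for a given date the window with the latest `effective_from` at or before
#' that date applies. `bed_time` earlier than `wake_time` denotes a window
#' crossing midnight.
#'
#' @param participant_id character.
#' @param wake_time,bed_time "HH:MM" strings (or integer minutes since midnight).
#' @param effective_from Date the window takes effect (defaults to the epoch,
#'   i.e. always in effect).
#' @return Validated tibble with integer minute-of-day columns.
#' @export
wake_windows <- function(participant_id, wake_time, bed_time,
                         effective_from = as.Date("1970-01-01")) {
  tod <- function(x) if (is.numeric(x)) as.integer(x) else parse_tod(x)
  df <- tibble::tibble(
    participant_id = as.character(participant_id),
    wake_min = tod(wake_time),
    bed_min = tod(bed_time),
    effective_from = as.Date(effective_from)
  )
  if (any(df$wake_min == df$bed_min)) {
    validation_error("wake_time must differ from bed_time (participant %s)",
                     df$participant_id[df$wake_min == df$bed_min][1])
  }
  if (any(df$wake_min < 0 | df$wake_min > 1439 | df$bed_min < 0 | df$bed_min > 1439)) {
    validation_error("times of day must lie in 00:00-23:59")
  }
  dplyr::arrange(df, .data$participant_id, .data$effective_from)
}

#' Assign perioperative phase to timestamps
#'
#' Study days partition into three phases: preoperative (before the surgery
#' date), inpatient (surgery date through discharge date, both inclusive),
#' and postdischarge (after the discharge date).
#'
#' @param t Date, POSIXct, or parseable timestamp vector.
#' @param surgery_date,discharge_date Dates (scalar or vectorized with `t`).
#' @return Factor with levels preoperative, inpatient, postdischarge.
#' @examples
#' assign_phase(as.Date("2023-03-05"), as.Date("2023-03-10"), as.Date("2023-03-20"))
#' @export
assign_phase <- function(t, surgery_date, discharge_date) {
  surgery_date <- as.Date(surgery_date)
  discharge_date <- as.Date(discharge_date)
  if (any(discharge_date < surgery_date)) {
    validation_error("discharge_date before surgery_date")
  }
  d <- if (inherits(t, "Date")) t else ts_date(if (inherits(t, "POSIXct")) t else parse_minute_ts(t))
  out <- ifelse(d < surgery_date, "preoperative",
                ifelse(d <= discharge_date, "inpatient", "postdischarge"))
  factor(out, levels = PHASES)
}

#' Perioperative phase levels
#' @format Character vector of length 3.
#' @export
PHASES <- c("preoperative", "inpatient", "postdischarge")

#' Read a participants configuration (YAML)
#'
#' Expects a top-level `participants:` list; each entry carries
#' `participant_id`, `arm` (intervention or monitoring), `surgery_date`,
#' `discharge_date`, `wake_time`, `bed_time`, and optionally `study_start`
#' and `study_end` dates delimiting the observation grid.
#'
#' @param path YAML file path.
#' @return Tibble with one row per participant.
#' @export
read_participants <- function(path) {
  y <- yaml::read_yaml(path)
  plist <- y$participants %||% y
  if (length(plist) == 0) validation_error("no participants in %s", path)
  rows <- lapply(plist, function(p) {
    tibble::tibble(
      participant_id = as.character(p$participant_id),
      arm = as.character(p$arm),
      surgery_date = as.Date(p$surgery_date),
      discharge_date = as.Date(p$discharge_date),
      wake_time = as.character(p$wake_time),
      bed_time = as.character(p$bed_time),
      study_start = as.Date(p$study_start %||% p$surgery_date),
      study_end = as.Date(p$study_end %||% p$discharge_date)
    )
  })
  df <- dplyr::bind_rows(rows)
  validate_participants(df)
}

#' Validate a participants tibble
#' @param df tibble as returned by [read_participants].
#' @return The validated tibble.
#' @export
validate_participants <- function(df) {
  need <- c("participant_id", "arm", "surgery_date", "discharge_date",
            "wake_time", "bed_time", "study_start", "study_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) validation_error("participants missing column(s): %s", paste(miss, collapse = ", "))
  if (any(duplicated(df$participant_id))) validation_error("duplicate participant_id")
  if (!all(df$arm %in% c("intervention", "monitoring"))) {
    validation_error("arm must be 'intervention' or 'monitoring'")
  }
  if (any(df$discharge_date < df$surgery_date)) validation_error("discharge_date before surgery_date")
  if (any(df$study_end < df$study_start)) validation_error("study_end before study_start")
  parse_tod(df$wake_time)  # errors on malformed times
  parse_tod(df$bed_time)
  df
}

#' Write a participants configuration YAML
#' @param df validated participants tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(df, path) {
  df <- validate_participants(df)
  plist <- lapply(seq_len(nrow(df)), function(i) {
    list(participant_id = df$participant_id[i],
         arm = df$arm[i],
         surgery_date = as.character(df$surgery_date[i]),
         discharge_date = as.character(df$discharge_date[i]),
         wake_time = df$wake_time[i],
         bed_time = df$bed_time[i],
         study_start = as.character(df$study_start[i]),
         study_end = as.character(df$study_end[i]))
  })
  yaml::write_yaml(list(participants = plist), path)
  invisible(path)
}

# Shared CSV reader: header check + per-row parse diagnostics.
#' @keywords internal
read_csv_checked <- function(path, need, col_types) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  raw <- suppressWarnings(  # parse problems are re-raised as classed errors below
    readr::read_csv(path, col_types = col_types %||% readr::cols(.default = readr::col_guess()),
                    progress = FALSE, show_col_types = FALSE)
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    parse_error("malformed row at line %d of %s: expected %s, got '%s'",
                probs$row[1] + 1L, path, probs$expected[1], probs$actual[1])
  }
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) parse_error("%s missing column(s): %s", path, paste(miss, collapse = ", "))
  raw
}
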