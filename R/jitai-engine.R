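# Real-time sedentary-behavior prompting engine.
#
# The engine watches a minute-level step stream. Minutes with fewer than the
# configured step cut (default 10 steps) are sedentary. Consecutive sedentary
# minutes accumulate; when the accumulator reaches the active threshold and
# the minute lies inside the participant's wake window, an activity prompt is
# emitted and the accumulator resets (reset-on-prompt). Any active minute
# fully resets the accumulator, as does the wake-window open. The threshold
# is re-evaluated each minute against the most recent symptom report: 60 min
# when all ten severities are below 7, 120 min when any is 7 or higher, and
# a conservative 120 min before any report exists. Steps accumulated in the
# 15 minutes strictly after a prompt determine the response: 30 or more
# trigger the positive feedback message.
#
# The production scan is closed-form over maximal sedentary runs (the first
# prompt in a constant-threshold sedentary block starting with accumulator
# `acc` falls at offset max(1, threshold - acc)); tests compare it against a
# brute-force per-minute re-scan on randomized days.

#' Classify minutes as sedentary or active
#'
#' A minute is sedentary when fewer than `cfg$sedentary_step_cut` steps were
#' logged (default 10, allowing for incidental stepping while classifying
#' very slow walking as activity).
#'
#' @param steps non-negative integer vector of per-minute step counts.
#' @param cfg an [engine_config()].
#' @return Character vector, "sedentary" or "active".
#' @examples
#' classify_minute(c(0, 9, 10, 250))
#' @export
classify_minute <- function(steps, cfg = engine_config()) {
  if (anyNA(steps) || any(steps < 0)) validation_error("steps must be non-negative")
  ifelse(steps < cfg$sedentary_step_cut, "sedentary", "active")
}

#' Threshold implied by the most recent symptom report
#'
#' All ten severities below `cfg$severity_cut` select the low (60-min)
#' threshold; any severity at or above it selects the high (120-min)
#' threshold; with no report ever submitted the configured conservative
#' default applies.
#'
#' @param report a one-row symptom-report tibble, a named numeric vector of
#'   the ten severities, or `NULL` when no report exists.
#' @param cfg an [engine_config()].
#' @return Threshold in minutes.
#' @examples
#' current_threshold(NULL)  # 120, unrated default
#' sev <- stats::setNames(rep(0, 10), SYMPTOM_DIMENSIONS)
#' current_threshold(sev)   # 60
#' @export
current_threshold <- function(report, cfg = engine_config()) {
  if (is.null(report)) return(cfg$default_threshold_when_unrated)
  if (is.data.frame(report)) {
    if (nrow(report) != 1) validation_error("report must have exactly one row")
    sev <- as.numeric(report[1, SYMPTOM_DIMENSIONS])
  } else {
    miss <- setdiff(SYMPTOM_DIMENSIONS, names(report))
    if (length(miss) > 0) validation_error("report missing severities: %s", paste(miss, collapse = ", "))
    sev <- as.numeric(report[SYMPTOM_DIMENSIONS])
  }
  if (anyNA(sev) || any(sev < 0) || any(sev > 10)) validation_error("severities must be in [0, 10]")
  if (any(sev >= cfg$severity_cut)) cfg$high_threshold else cfg$low_threshold
}

# First prompt in [from, to] given accumulator 0 at `from` (a reset just
# occurred there). Only the [from, to] slice of `steps` is touched so the
# cost of a scan is proportional to the distance to the next prompt.
#' @keywords internal
next_prompt_range <- function(steps, thr, from, to, cut) {
  if (from > to) return(NULL)
  r <- rle(steps[from:to] < cut)
  ends <- cumsum(r$lengths) + from - 1L
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next  # active or out-of-window run: accumulator reset
    acc <- 0L
    i <- starts[k]
    rend <- ends[k]
    while (i <= rend) {
      thr_here <- thr[i]
      chg <- which(thr[i:rend] != thr_here)
      bend <- if (length(chg) == 0) rend else i + chg[1] - 2L
      len <- bend - i + 1L
      first <- max(1L, thr_here - acc)
      if (len >= first) return(list(idx = i + first - 1L, thr = thr_here))
      acc <- acc + len
      i <- bend + 1L
    }
  }
  NULL
}

# Engine over a full participant grid. `in_window` marks waking minutes;
# accumulation happens only there (the accumulator is implicitly reset at
# window open and by any out-of-window minute). `respond_cb(idx, thr)` lets
# the cohort simulator inject or suppress post-prompt behavior; it may return
# list(idx=, steps=) modifications which the engine applies before tallying
# the response window.
#' @keywords internal
run_engine_core <- function(steps, thr, in_window, cfg, respond_cb = NULL) {
  cut <- cfg$sedentary_step_cut
  n <- length(steps)
  seg <- rle(in_window)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1L
  ev <- list()
  for (k in which(seg$values)) {
    cursor <- seg_start[k]
    e <- seg_end[k]
    repeat {
      np <- next_prompt_range(steps, thr, cursor, e, cut)
      if (is.null(np)) break
      m <- np$idx
      if (!is.null(respond_cb)) {
        mod <- respond_cb(m, np$thr)
        if (!is.null(mod)) steps[mod$idx] <- as.integer(mod$steps)
      }
      we <- min(m + cfg$response_window, n)
      rs <- if (we > m) sum(steps[(m + 1L):we]) else 0L
      ev[[length(ev) + 1L]] <- c(m, np$thr, rs)
      cursor <- m + 1L
    }
  }
  if (length(ev) == 0) {
    evm <- matrix(integer(0), ncol = 3)
  } else {
    evm <- do.call(rbind, ev)
  }
  responded <- evm[, 3] >= cfg$response_step_goal
  list(idx = as.integer(evm[, 1]), threshold_used = as.integer(evm[, 2]),
       responded = responded, response_steps = as.integer(evm[, 3]),
       feedback_sent = responded, steps = steps)
}

# Per-minute threshold series from a participant's symptom reports (carried
# forward indefinitely; default before the first report).
#' @keywords internal
threshold_series <- function(n, t0, reports, cfg) {
  if (is.null(reports) || nrow(reports) == 0) {
    return(rep(cfg$default_threshold_when_unrated, n))
  }
  sev <- as.matrix(reports[SYMPTOM_DIMENSIONS])
  high <- apply(sev >= cfg$severity_cut, 1, any)
  rsec <- as.numeric(reports$timestamp)
  o <- order(rsec)
  rsec <- rsec[o]
  high <- high[o]
  gsec <- as.numeric(t0) + (seq_len(n) - 1) * MINUTE
  k <- findInterval(gsec, rsec)
  thr <- ifelse(high[pmax(k, 1L)], cfg$high_threshold, cfg$low_threshold)
  thr[k == 0L] <- cfg$default_threshold_when_unrated
  as.integer(thr)
}

# Minute grid for one participant over [start_date, end_date]: positions of
# waking-window minutes and the waking-day date each belongs to (a window
# crossing midnight is attributed to its opening date).
#' @keywords internal
build_grid <- function(pid, start_date, end_date, windows) {
  ndays <- as.integer(end_date - start_date) + 1L
  if (ndays < 1) validation_error("end_date before start_date")
  n <- ndays * 1440L
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  w <- windows[windows$participant_id == pid, , drop = FALSE]
  if (nrow(w) == 0) validation_error("no wake window for participant %s", pid)
  in_window <- rep(FALSE, n)
  day <- rep(as.Date(NA), n)
  dates <- seq(start_date, end_date, by = "day")
  ki <- findInterval(as.numeric(dates), as.numeric(w$effective_from))
  if (any(ki == 0)) validation_error("no wake window in effect on %s for %s",
                                     dates[ki == 0][1], pid)
  for (d in seq_len(ndays)) {
    wake <- w$wake_min[ki[d]]
    len <- (w$bed_min[ki[d]] - wake) %% 1440L
    s <- (d - 1L) * 1440L + wake + 1L
    e <- min(s + len - 1L, n)
    idx <- s:e
    in_window[idx] <- TRUE
    day[idx] <- dates[d]
  }
  list(t0 = t0, n = n, in_window = in_window, day = day,
       time = t0 + (seq_len(n) - 1) * MINUTE)
}

# Restrict a grid to [from, to] (minute timestamps).
#' @keywords internal
trim_grid <- function(grid, from, to) {
  a <- max(1L, as.integer((as.numeric(from) - as.numeric(grid$t0)) / MINUTE) + 1L)
  b <- min(grid$n, as.integer((as.numeric(to) - as.numeric(grid$t0)) / MINUTE) + 1L)
  list(t0 = grid$t0 + (a - 1L) * MINUTE, n = b - a + 1L,
       in_window = grid$in_window[a:b], day = grid$day[a:b],
       time = grid$time[a:b])
}

# Map stream rows onto a grid; missing minutes get zero steps / not worn.
#' @keywords internal
grid_steps <- function(stream, grid) {
  steps <- integer(grid$n)
  worn <- logical(grid$n)
  present <- logical(grid$n)
  if (nrow(stream) > 0) {
    idx <- as.integer((as.numeric(stream$timestamp) - as.numeric(grid$t0)) / MINUTE) + 1L
    keep <- idx >= 1L & idx <= grid$n
    steps[idx[keep]] <- stream$steps[keep]
    worn[idx[keep]] <- stream$worn[keep]
    present[idx[keep]] <- TRUE
  }
  list(steps = steps, worn = worn, present = present)
}

#' @keywords internal
empty_events <- function() {
  tibble::tibble(participant_id = character(0),
                 timestamp = as.POSIXct(character(0), tz = "UTC"),
                 threshold_used = integer(0), responded = logical(0),
                 response_steps = integer(0), feedback_sent = logical(0))
}

#' @keywords internal
events_tibble <- function(pid, grid, core) {
  tibble::tibble(
    participant_id = rep(pid, length(core$idx)),
    timestamp = grid$time[core$idx],
    threshold_used = core$threshold_used,
    responded = core$responded,
    response_steps = core$response_steps,
    feedback_sent = core$feedback_sent
  )
}

#' Run the prompting engine over one participant-day
#'
#' Processes a single day's minute stream through the sedentary-accumulation
#' state machine and returns the prompts emitted plus the engine state at the
#' end of the day. Minutes absent from the stream are treated as zero-step
#' (sedentary) minutes, matching an on-wrist app that sees no steps while
#' idle.
#'
#' @param stream minute-stream tibble for one participant-day.
#' @param reports symptom-report tibble for the participant (reports from
#'   earlier days carry forward; may be empty).
#' @param window a [wake_windows()] tibble (one participant).
#' @param cfg an [engine_config()].
#' @return List with `events` (prompt-event tibble) and `state` (list with
#'   `sedentary_accumulator`, `active_threshold`, `last_symptom_report`).
#' @export
step_engine <- function(stream, reports = NULL, window, cfg = engine_config()) {
  stream <- validate_minute_stream(stream)
  pid <- unique(c(stream$participant_id, window$participant_id))
  if (length(pid) > 1) validation_error("stream and window must belong to one participant")
  if (nrow(stream) == 0) validation_error("empty stream")
  if (is.unsorted(as.numeric(stream$timestamp))) validation_error("stream must be sorted")
  start_date <- ts_date(min(stream$timestamp))
  end_date <- ts_date(max(stream$timestamp))
  grid <- build_grid(pid, start_date, end_date, window)
  g <- grid_steps(stream, grid)
  if (!is.null(reports) && nrow(reports) > 0) {
    reports <- validate_symptom_reports(reports)
    if (any(reports$participant_id != pid)) validation_error("reports from a different participant")
  }
  thr <- threshold_series(grid$n, grid$t0, reports, cfg)
  core <- run_engine_core(g$steps, thr, grid$in_window, cfg)
  events <- events_tibble(pid, grid, core)

  # End-of-day accumulator: trailing sedentary minutes inside the last open
  # window segment since the most recent reset (active minute or prompt).
  acc <- 0L
  n <- grid$n
  if (grid$in_window[n]) {
    seg_start <- n
    while (seg_start > 1 && grid$in_window[seg_start - 1L]) seg_start <- seg_start - 1L
    resets <- c(seg_start - 1L,
                which(core$steps >= cfg$sedentary_step_cut & seq_len(n) >= seg_start),
                core$idx)
    acc <- n - max(resets)
  }
  last_rep <- NULL
  if (!is.null(reports) && nrow(reports) > 0) {
    before <- reports[as.numeric(reports$timestamp) <= as.numeric(grid$time[n]), , drop = FALSE]
    if (nrow(before) > 0) last_rep <- before[nrow(before), , drop = FALSE]
  }
  state <- list(
    sedentary_accumulator = as.integer(acc),
    active_threshold = thr[n],
    last_symptom_report = last_rep
  )
  list(events = events, state = state)
}

#' Run the prompting engine over a participant's full timeline
#'
#' Multi-day driver: builds the complete minute grid between `start_date`
#' and `end_date` (defaulting to the stream's extent), treats missing
#' minutes as zero-step, gates prompts on the wake window (engine state
#' resets at each window open), and returns all emitted prompt events in
#' time order. Monitoring-arm participants receive no prompts; the engine is
#' not invoked and an empty event table is returned.
#'
#' @param stream minute-stream tibble (one participant).
#' @param reports symptom-report tibble (may be `NULL` or empty).
#' @param windows a [wake_windows()] tibble.
#' @param cfg an [engine_config()].
#' @param arm "intervention" or "monitoring".
#' @param start_date,end_date Dates delimiting the grid (default: stream extent).
#' @return Prompt-event tibble.
#' @export
run_participant <- function(stream, reports = NULL, windows, cfg = engine_config(),
                            arm = "intervention", start_date = NULL, end_date = NULL) {
  stream <- validate_minute_stream(stream)
  pid <- unique(stream$participant_id)
  if (length(pid) != 1) validation_error("run_participant expects exactly one participant")
  if (identical(arm, "monitoring")) return(empty_events())
  # with explicit dates the grid spans whole days (missing minutes are
  # zero-step); by default it is trimmed to the observed extent so minutes
  # before the first or after the last sample are not invented
  trim <- is.null(start_date) && is.null(end_date)
  start_date <- as.Date(start_date %||% ts_date(min(stream$timestamp)))
  end_date <- as.Date(end_date %||% ts_date(max(stream$timestamp)))
  grid <- build_grid(pid, start_date, end_date, windows)
  if (trim) grid <- trim_grid(grid, min(stream$timestamp), max(stream$timestamp))
  g <- grid_steps(stream, grid)
  if (!is.null(reports) && nrow(reports) > 0) {
    reports <- validate_symptom_reports(reports)
    reports <- reports[reports$participant_id == pid, , drop = FALSE]
  }
  thr <- threshold_series(grid$n, grid$t0, reports, cfg)
  core <- run_engine_core(g$steps, thr, grid$in_window, cfg)
  events_tibble(pid, grid, core)
}
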