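# Adherence and objective-activity outcomes.
#
# Daily metrics follow the trial's measurement rules: a day enters activity
# analyses when at least 480 worn minutes (8 h, not necessarily consecutive)
# were logged; sedentary bouts are maximal runs of sub-threshold minutes
# within the waking day, with device-detected sleep removed before run
# finding; missing minutes count as sedentary by default (a wrist device
# logs zero steps while idle or off wrist). Phase-level response fractions
# are pooled ratio-of-sums, matching the way engagement counts such as
# 418/1925 are reported, not means of daily ratios.

#' Worn minutes in one participant-day
#'
#' @param day_stream minute-stream tibble for one participant-day.
#' @return Count of minutes with `worn = TRUE`.
#' @export
daily_wear_minutes <- function(day_stream) {
  if (nrow(day_stream) == 0) return(0L)
  day_stream <- validate_minute_stream(day_stream)
  sum(day_stream$worn)
}

#' Extract sedentary bouts for one participant-day
#'
#' Finds maximal runs of sedentary minutes (fewer than `sedentary_step_cut`
#' steps) within the waking window. Minutes inside sleep episodes are
#' removed before run-finding when `cfg$exclude_sleep`, splitting runs at
#' episode boundaries; minutes with no recorded sample count as sedentary
#' when `cfg$treat_missing_as_sedentary`, otherwise they break runs.
#'
#' @param day_stream minute-stream tibble for one participant-day.
#' @param window a [wake_windows()] tibble for the participant.
#' @param sleep sleep-episode tibble (may be `NULL`).
#' @param cfg a [metrics_config()].
#' @param sedentary_step_cut steps/min below which a minute is sedentary (10).
#' @param date waking-day date; defaults to the date of the first sample.
#' @return Tibble with columns `start` (timestamp) and `duration` (minutes).
#' @export
extract_bouts <- function(day_stream, window, sleep = NULL, cfg = metrics_config(),
                          sedentary_step_cut = 10L, date = NULL) {
  day_stream <- validate_minute_stream(day_stream)
  pid <- unique(c(day_stream$participant_id, window$participant_id))
  if (length(pid) > 1) validation_error("stream and window must belong to one participant")
  if (!is.null(sleep) && nrow(sleep) > 0) sleep <- validate_sleep_episodes(sleep)
  date <- as.Date(date %||% ts_date(min(day_stream$timestamp)))
  grid <- build_grid(pid, date, date + 1L, window)  # +1 day for windows crossing midnight
  g <- grid_steps(day_stream, grid)
  sed <- sedentary_flags(g, grid, sleep, cfg, sedentary_step_cut, day_filter = date)
  bouts_from_flags(sed, grid)
}

# Per-minute "counts toward a sedentary bout" flags on a grid.
#' @keywords internal
sedentary_flags <- function(g, grid, sleep, cfg, cut, day_filter = NULL) {
  sed_minute <- ifelse(g$present, g$steps < cut, cfg$treat_missing_as_sedentary)
  flags <- grid$in_window & sed_minute
  if (!is.null(day_filter)) flags <- flags & !is.na(grid$day) & grid$day == day_filter
  if (cfg$exclude_sleep && !is.null(sleep) && nrow(sleep) > 0) {
    t0n <- as.numeric(grid$t0)
    for (i in seq_len(nrow(sleep))) {
      a <- max(1L, as.integer((as.numeric(sleep$start[i]) - t0n) / MINUTE) + 1L)
      b <- min(grid$n, as.integer((as.numeric(sleep$end[i]) - t0n) / MINUTE))
      if (a <= b) flags[a:b] <- FALSE
    }
  }
  flags
}

#' @keywords internal
bouts_from_flags <- function(flags, grid) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start = grid$time[starts[keep]],
    duration = as.integer(r$lengths[keep]),
    date = grid$day[starts[keep]]
  )[, c("start", "duration", "date")]
}

#' Summarize one participant-day
#'
#' Populates the daily summary used throughout the package: worn minutes,
#' total steps, sedentary bouts with their daily mean and maximum, prompt
#' and response counts, whether a symptom rating was completed, and the
#' 8-hour wear-filter inclusion flag.
#'
#' @param day_stream minute-stream tibble for one participant-day.
#' @param events prompt events for the day (may be `NULL`).
#' @param reports symptom reports for the day (may be `NULL`).
#' @param window a [wake_windows()] tibble.
#' @param sleep sleep episodes (may be `NULL`).
#' @param cfg a [metrics_config()].
#' @param sedentary_step_cut steps/min below which a minute is sedentary.
#' @param date the day; defaults to the date of the first sample.
#' @return One-row tibble (see package overview for fields).
#' @export
summarize_day <- function(day_stream, events = NULL, reports = NULL, window,
                          sleep = NULL, cfg = metrics_config(),
                          sedentary_step_cut = 10L, date = NULL) {
  day_stream <- validate_minute_stream(day_stream)
  pid <- unique(day_stream$participant_id)
  if (length(pid) != 1) validation_error("summarize_day expects one participant")
  date <- as.Date(date %||% ts_date(min(day_stream$timestamp)))
  if (length(unique(ts_date(day_stream$timestamp))) > 1) {
    validation_error("summarize_day received cross-day data")
  }
  bouts <- extract_bouts(day_stream, window, sleep, cfg, sedentary_step_cut, date)
  n_prompts <- 0L
  n_responses <- 0L
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events[events$participant_id == pid & ts_date(events$timestamp) == date, , drop = FALSE]
    n_prompts <- nrow(ev)
    n_responses <- sum(ev$responded)
  }
  reported <- !is.null(reports) && nrow(reports) > 0 &&
    any(reports$participant_id == pid & ts_date(reports$timestamp) == date)
  wear <- daily_wear_minutes(day_stream)
  tibble::tibble(
    participant_id = pid,
    date = date,
    wear_minutes = as.integer(wear),
    total_steps = sum(day_stream$steps),
    n_bouts = nrow(bouts),
    max_bout = if (nrow(bouts) > 0) max(bouts$duration) else 0,
    mean_bout = if (nrow(bouts) > 0) mean(bouts$duration) else 0,
    n_prompts = as.integer(n_prompts),
    n_responses = as.integer(n_responses),
    symptom_reported = reported,
    included = wear >= cfg$min_wear_minutes
  )
}

#' Daily summaries for a whole cohort
#'
#' Vectorized driver over every participant-day between each participant's
#' `study_start` and `study_end`. Days with no recorded samples still appear
#' (zero wear, excluded by the wear filter) so adherence denominators count
#' all study days.
#'
#' @param stream minute-stream tibble (all participants).
#' @param reports symptom-report tibble.
#' @param events prompt-event tibble.
#' @param sleep sleep-episode tibble.
#' @param participants participants tibble (see [read_participants]).
#' @param cfg a [metrics_config()].
#' @param sedentary_step_cut steps/min below which a minute is sedentary.
#' @return Tibble with one row per participant-day, including `phase` and `arm`.
#' @export
summarize_days <- function(stream, reports = NULL, events = NULL, sleep = NULL,
                           participants, cfg = metrics_config(),
                           sedentary_step_cut = 10L) {
  stream <- validate_minute_stream(stream)
  participants <- validate_participants(participants)
  windows <- wake_windows(participants$participant_id, participants$wake_time,
                          participants$bed_time)
  out <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    pid <- p$participant_id
    grid <- build_grid(pid, p$study_start, p$study_end, windows)
    g <- grid_steps(stream[stream$participant_id == pid, , drop = FALSE], grid)
    slp <- if (!is.null(sleep) && nrow(sleep) > 0) sleep[sleep$participant_id == pid, , drop = FALSE] else NULL
    flags <- sedentary_flags(g, grid, slp, cfg, sedentary_step_cut)
    bouts <- bouts_from_flags(flags, grid)

    dates <- seq(p$study_start, p$study_end, by = "day")
    cal_date <- rep(dates, each = 1440L)
    wear <- tapply_int(g$worn, cal_date, dates)
    steps <- tapply_int(g$steps * g$present, cal_date, dates)
    bmax <- rep(0, length(dates))
    bmean <- rep(0, length(dates))
    bn <- rep(0L, length(dates))
    if (nrow(bouts) > 0) {
      agg <- dplyr::summarise(dplyr::group_by(bouts, .data$date),
                              bmax = max(.data$duration),
                              bmean = mean(.data$duration),
                              bn = dplyr::n())
      j <- match(agg$date, dates)
      bmax[j] <- agg$bmax; bmean[j] <- agg$bmean; bn[j] <- agg$bn
    }
    np <- rep(0L, length(dates)); nr <- rep(0L, length(dates))
    if (!is.null(events) && nrow(events) > 0) {
      ev <- events[events$participant_id == pid, , drop = FALSE]
      if (nrow(ev) > 0) {
        ed <- ts_date(ev$timestamp)
        np <- tapply_int(rep(1L, nrow(ev)), ed, dates)
        nr <- tapply_int(as.integer(ev$responded), ed, dates)
      }
    }
    reported <- rep(FALSE, length(dates))
    if (!is.null(reports) && nrow(reports) > 0) {
      rp <- reports[reports$participant_id == pid, , drop = FALSE]
      if (nrow(rp) > 0) reported <- dates %in% ts_date(rp$timestamp)
    }
    out[[i]] <- tibble::tibble(
      participant_id = pid,
      arm = p$arm,
      date = dates,
      phase = assign_phase(dates, p$surgery_date, p$discharge_date),
      wear_minutes = wear,
      total_steps = steps,
      n_bouts = bn,
      max_bout = as.numeric(bmax),
      mean_bout = bmean,
      n_prompts = np,
      n_responses = nr,
      symptom_reported = reported,
      included = wear >= cfg$min_wear_minutes
    )
  }
  dplyr::bind_rows(out)
}

# Sum `x` over factor `by` aligned to the full `levels` vector of dates.
#' @keywords internal
tapply_int <- function(x, by, levels) {
  s <- rowsum(as.integer(x), group = as.integer(by), reorder = TRUE)
  out <- rep(0L, length(levels))
  j <- match(as.integer(rownames(s)), as.integer(levels))
  keep <- !is.na(j)
  out[j[keep]] <- as.integer(s[keep, 1])
  out
}

#' Phase-level summaries
#'
#' Aggregates daily summaries by perioperative phase. Step and bout means
#' use wear-filter-included days only; prompt counts average over all phase
#' days; the response fraction is pooled (sum of responses over sum of
#' prompts), and is `NA` when a phase has no prompts.
#'
#' @param summaries daily-summary tibble from [summarize_days()].
#' @param by optional extra grouping column name (e.g. "arm").
#' @return One row per phase (and `by` group).
#' @export
summarize_phase <- function(summaries, by = NULL) {
  g <- dplyr::group_by(summaries, .data$phase,
                       !!!(if (is.null(by)) NULL else rlang::syms(by)))
  dplyr::ungroup(dplyr::summarise(
    g,
    n_days = dplyr::n(),
    n_included_days = sum(.data$included),
    mean_steps = mean(.data$total_steps[.data$included]),
    mean_of_daily_mean_bout = mean(.data$mean_bout[.data$included]),
    mean_of_daily_max_bout = mean(.data$max_bout[.data$included]),
    prompts_per_day = mean(.data$n_prompts),
    n_prompts = sum(.data$n_prompts),
    n_responses = sum(.data$n_responses),
    response_fraction = ifelse(sum(.data$n_prompts) > 0,
                               sum(.data$n_responses) / sum(.data$n_prompts), NA_real_),
    symptom_adherence_fraction = mean(.data$symptom_reported),
    wear_adherence_fraction = mean(.data$included),
    .groups = "drop"
  ))
}

#' Cohort adherence report
#'
#' Numerator/denominator/percentage (rounded half away from zero) for the
#' trial's adherence definitions: days with a completed symptom rating, days
#' the device was worn at all, days with at least 8 hours of wear among worn
#' days, days included overall, and the pooled prompt-response fraction.
#' Per-participant minima and maxima of the daily adherence rates are
#' attached.
#'
#' @param summaries daily-summary tibble from [summarize_days()].
#' @return List of class `sedprompt_adherence`.
#' @export
adherence_table <- function(summaries) {
  frac <- function(num, den) {
    list(numerator = as.integer(num), denominator = as.integer(den),
         fraction = if (den > 0) num / den else NA_real_,
         percent = if (den > 0) round_half_up(100 * num / den) else NA_real_)
  }
  n_days <- nrow(summaries)
  worn <- sum(summaries$wear_minutes > 0)
  ge8 <- sum(summaries$included)
  per <- dplyr::summarise(
    dplyr::group_by(summaries, .data$participant_id),
    symptom = mean(.data$symptom_reported),
    included = mean(.data$included),
    .groups = "drop"
  )
  out <- list(
    symptom_days = frac(sum(summaries$symptom_reported), n_days),
    worn_days = frac(worn, n_days),
    wear8h_among_worn = frac(ge8, worn),
    included_days = frac(ge8, n_days),
    prompt_response = frac(sum(summaries$n_responses), sum(summaries$n_prompts)),
    per_participant = list(
      symptom_min = min(per$symptom), symptom_max = max(per$symptom),
      included_min = min(per$included), included_max = max(per$included)
    )
  )
  structure(out, class = "sedprompt_adherence")
}

#' @export
print.sedprompt_adherence <- function(x, ...) {
  line <- function(label, f) {
    cat(sprintf("  %-24s %d/%d (%s%%)\n", label, f$numerator, f$denominator,
                ifelse(is.na(f$percent), "NA", format(f$percent))))
  }
  cat("Adherence report\n")
  line("symptom-rating days", x$symptom_days)
  line("worn days", x$worn_days)
  line(">=8 h among worn days", x$wear8h_among_worn)
  line("included days", x$included_days)
  if (x$prompt_response$denominator > 0) line("prompts responded", x$prompt_response)
  pp <- x$per_participant
  cat(sprintf("  per-participant symptom adherence: %.0f%%-%.0f%%\n",
              100 * pp$symptom_min, 100 * pp$symptom_max))
  cat(sprintf("  per-participant included days:     %.0f%%-%.0f%%\n",
              100 * pp$included_min, 100 * pp$included_max))
  invisible(x)
}
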