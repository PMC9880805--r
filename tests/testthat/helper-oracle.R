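# Independent brute-force oracles and randomized day generators.
#
# The oracles re-derive engine and bout behavior with per-minute loops and
# their own threshold bookkeeping; they share no code with the package's
# closed-form scan.

DAY0 <- as.Date("2023-03-06")

# Per-minute engine re-scan over one day grid (1440 minutes). Reports are
# (minute index <= 1440, severe flag) pairs; indices <= 0 encode reports
# carried in from earlier days.
oracle_engine_day <- function(steps, in_window, report_min = integer(0),
                              report_high = logical(0), cfg = engine_config()) {
  n <- length(steps)
  thr_cur <- cfg$default_threshold_when_unrated
  k <- 1L
  acc <- 0L
  idx <- integer(0); thr_used <- integer(0); resp <- integer(0)
  for (i in seq_len(n)) {
    while (k <= length(report_min) && report_min[k] <= i) {
      thr_cur <- if (report_high[k]) cfg$high_threshold else cfg$low_threshold
      k <- k + 1L
    }
    if (!in_window[i]) { acc <- 0L; next }
    if (steps[i] >= cfg$sedentary_step_cut) { acc <- 0L; next }
    acc <- acc + 1L
    if (acc >= thr_cur) {
      we <- min(i + cfg$response_window, n)
      idx <- c(idx, i)
      thr_used <- c(thr_used, thr_cur)
      resp <- c(resp, if (we > i) sum(steps[(i + 1):we]) else 0L)
      acc <- 0L
    }
  }
  tibble::tibble(idx = idx, threshold_used = thr_used, response_steps = resp,
                 responded = resp >= cfg$response_step_goal)
}

# Per-minute bout re-scan: returns durations of maximal sedentary runs.
oracle_bout_durations <- function(present, steps, in_window, asleep,
                                  treat_missing = TRUE, cut = 10L) {
  durs <- integer(0)
  cur <- 0L
  for (i in seq_along(steps)) {
    sed <- in_window[i] && !asleep[i] &&
      (if (present[i]) steps[i] < cut else treat_missing)
    if (sed) {
      cur <- cur + 1L
    } else if (cur > 0L) {
      durs <- c(durs, cur); cur <- 0L
    }
  }
  if (cur > 0L) durs <- c(durs, cur)
  durs
}

# Random single-day scenario with run-structured activity, gaps, naps, and
# 0-3 symptom reports. Returns vectors plus the package-facing tibbles.
random_day <- function(pid = "P1") {
  wake <- sample(300:540, 1)
  len <- sample(600:850, 1)
  in_window <- rep(FALSE, 1440L)
  in_window[(wake + 1):(wake + len)] <- TRUE

  # alternating sedentary/active runs covering the day
  steps <- integer(1440L)
  i <- 1L
  sedent <- runif(1) < 0.7
  while (i <= 1440L) {
    l <- if (sedent) rgeom(1, 1 / 80) + 1L else rgeom(1, 1 / 8) + 1L
    j <- min(1440L, i + l - 1L)
    steps[i:j] <- if (sedent) sample(0:9, j - i + 1L, replace = TRUE)
                  else sample(10:120, j - i + 1L, replace = TRUE)
    sedent <- !sedent
    i <- j + 1L
  }
  present <- runif(1440L) > 0.05
  # a contiguous non-wear gap
  if (runif(1) < 0.5) {
    gs <- sample(1:1300, 1)
    present[gs:min(1440L, gs + sample(30:240, 1))] <- FALSE
  }
  nrep <- sample(0:3, 1)
  report_min <- sort(sample(1:1440, nrep))
  report_high <- runif(nrep) < 0.5
  # possibly a report carried over from the previous day
  if (runif(1) < 0.5) {
    report_min <- c(0L, report_min)
    report_high <- c(runif(1) < 0.5, report_high)
  }
  asleep <- rep(FALSE, 1440L)
  if (runif(1) < 0.6) {
    ns <- sample(1:1350, 1)
    asleep[ns:min(1440L, ns + sample(20:90, 1))] <- TRUE
  }
  list(pid = pid, wake = wake, len = len, in_window = in_window,
       steps = steps, present = present, asleep = asleep,
       report_min = report_min, report_high = report_high)
}

# Package-facing inputs for a random_day scenario.
day_inputs <- function(d) {
  t0 <- as.POSIXct(paste(DAY0, "00:00:00"), tz = "UTC")
  mins <- which(d$present)
  stream <- tibble::tibble(
    participant_id = d$pid,
    timestamp = t0 + (mins - 1) * 60,
    steps = d$steps[mins],
    worn = TRUE
  )
  nrep <- length(d$report_min)
  reports <- NULL
  if (nrep > 0) {
    sev <- matrix(sample(0:5, nrep * 10L, replace = TRUE), nrow = nrep,
                  dimnames = list(NULL, SYMPTOM_DIMENSIONS))
    sev[, "pain"] <- ifelse(d$report_high, 9L, sample(0:6, nrep, replace = TRUE))
    reports <- symptom_reports(rep(d$pid, nrep),
                               t0 + (d$report_min - 1) * 60,
                               tibble::as_tibble(sev))
  }
  bed <- (d$wake + d$len) %% 1440L
  window <- wake_windows(d$pid, d$wake, bed)
  sleep <- NULL
  if (any(d$asleep)) {
    r <- rle(d$asleep)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    keep <- r$values
    sleep <- sleep_episodes(rep(d$pid, sum(keep)),
                            t0 + (s[keep] - 1) * 60, t0 + e[keep] * 60)
  }
  list(t0 = t0, stream = stream, reports = reports, window = window, sleep = sleep)
}

# Steps vector with missing minutes zeroed, as the engine sees the day.
engine_steps <- function(d) ifelse(d$present, d$steps, 0L)

# Fully sedentary single-day stream over [start_min, end_min] minutes of DAY0.
flat_day_stream <- function(pid = "P1", date = DAY0, steps = 0L) {
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  tibble::tibble(participant_id = pid, timestamp = t0 + (0:1439) * 60,
                 steps = as.integer(steps), worn = TRUE)
}

# One-day reports tibble: a single morning rating, severe or not.
morning_report <- function(pid = "P1", date = DAY0, severe = FALSE, minute = 435) {
  sev <- stats::setNames(as.list(rep(2L, 10)), SYMPTOM_DIMENSIONS)
  if (severe) sev$fatigue <- 8L
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  symptom_reports(pid, t0 + (minute - 1) * 60, tibble::as_tibble(sev))
}

# n samples with exactly the requested mean and sd (for t-test cross-checks).
exact_sample <- function(n, mean, sd) {
  x <- seq_len(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}
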