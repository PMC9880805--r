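low_sev <- function(v = 6L) stats::setNames(rep(v, 10), SYMPTOM_DIMENSIONS)

test_that("minute classification uses the sub-10-step rule", {
  expect_equal(classify_minute(9L), "sedentary")
  expect_equal(classify_minute(10L), "active")
  expect_equal(classify_minute(0L), "sedentary")
  expect_equal(classify_minute(c(0, 9, 10, 300)),
               c("sedentary", "sedentary", "active", "active"))
  expect_error(classify_minute(-1L), class = "sedprompt_validation_error")
})

test_that("threshold selection follows the severity-7 cut with a conservative default", {
  expect_equal(current_threshold(low_sev(6L)), 60L)
  sev <- low_sev(0L); sev["nausea"] <- 7L
  expect_equal(current_threshold(sev), 120L)
  expect_equal(current_threshold(NULL), 120L)
  expect_equal(current_threshold(low_sev(7L)), 120L)
  expect_error(current_threshold(low_sev(12L)), class = "sedprompt_validation_error")
})

test_that("a fully sedentary 12-h day yields prompts at exact threshold intervals", {
  stream <- flat_day_stream(steps = 0L)
  window <- wake_windows("P1", "08:00", "20:00")

  # all symptoms mild -> 60-min threshold -> 12 prompts at 60-min spacing
  res <- step_engine(stream, morning_report(minute = 1), window)
  expect_equal(nrow(res$events), 12)
  mins <- as.integer(format(res$events$timestamp, "%H")) * 60 +
    as.integer(format(res$events$timestamp, "%M"))
  expect_equal(mins, 8 * 60 + seq(60, 720, by = 60) - 1)
  expect_equal(unique(res$events$threshold_used), 60L)
  expect_false(any(res$events$responded))

  # any severe symptom -> 120-min threshold -> 6 prompts
  res2 <- step_engine(stream, morning_report(severe = TRUE, minute = 1), window)
  expect_equal(nrow(res2$events), 6)
  expect_equal(unique(res2$events$threshold_used), 120L)

  # never rated -> conservative 120-min default
  res3 <- step_engine(stream, NULL, window)
  expect_equal(nrow(res3$events), 6)
})

test_that("response detection tallies the 15 minutes strictly after the prompt", {
  steps <- rep(0L, 1440)
  window <- wake_windows("P1", "08:00", "20:00")
  # first prompt at in-window minute 60 => grid minute 540 (index from 1)
  prompt_idx <- 8 * 60 + 60
  steps[prompt_idx + 3] <- 15L
  steps[prompt_idx + 7] <- 20L
  stream <- flat_day_stream(steps = steps)
  res <- step_engine(stream, morning_report(minute = 1), window)
  expect_true(res$events$responded[1])
  expect_true(res$events$feedback_sent[1])
  expect_equal(res$events$response_steps[1], 35L)

  steps2 <- rep(0L, 1440)
  steps2[prompt_idx + 15] <- 29L  # boundary: 29 < 30, inside (t, t+15]
  res2 <- step_engine(flat_day_stream(steps = steps2),
                      morning_report(minute = 1), window)
  expect_false(res2$events$responded[1])
  expect_false(res2$events$feedback_sent[1])
})

test_that("multi-day driver resets state at each wake-window open", {
  t0 <- as.POSIXct(paste(DAY0, "00:00:00"), tz = "UTC")
  stream <- minute_stream("P1", t0 + (0:(2 * 1440 - 1)) * 60, 0L, TRUE)
  window <- wake_windows("P1", "08:00", "20:00")
  rep2 <- morning_report(minute = 1)
  ev <- run_participant(stream, rep2, window)
  expect_equal(nrow(ev), 24)  # 2 x 12
  expect_equal(sum(as.Date(ev$timestamp) == DAY0), 12)

  # monitoring arm: engine not invoked
  expect_equal(nrow(run_participant(stream, rep2, window, arm = "monitoring")), 0)

  # observed data entirely outside the wake window: no prompts
  night <- minute_stream("P1", t0 + (0:419) * 60, 0L, TRUE)  # 00:00-06:59
  expect_equal(nrow(run_participant(night, rep2, window)), 0)
})

test_that("prompt count on a flat day equals floor(waking minutes / threshold)", {
  set.seed(52)
  for (i in 1:20) {
    wake <- sample(240:600, 1)
    wlen <- sample(300:1000, 1)
    wlen <- min(wlen, 1439 - wake)
    severe <- runif(1) < 0.5
    thr <- if (severe) 120L else 60L
    stream <- flat_day_stream(steps = 0L)
    window <- wake_windows("P1", wake, wake + wlen)
    res <- step_engine(stream, morning_report(severe = severe, minute = 1), window)
    expect_equal(nrow(res$events), floor(wlen / thr))
  }
})

test_that("threshold changes mid-accumulation apply without resetting the accumulator", {
  # severe rating arrives at in-window minute 50 while accumulating under the
  # 60-min threshold: the ongoing bout must now reach 120 minutes
  stream <- flat_day_stream(steps = 0L)
  window <- wake_windows("P1", "08:00", "20:00")
  reports <- dplyr::bind_rows(
    morning_report(minute = 1),
    morning_report(severe = TRUE, minute = 8 * 60 + 50)
  )
  res <- step_engine(stream, reports, window)
  mins <- as.integer(format(res$events$timestamp, "%H")) * 60 +
    as.integer(format(res$events$timestamp, "%M"))
  expect_equal(mins[1] - (8 * 60 - 1), 120)  # first prompt at accumulated 120
  expect_equal(res$events$threshold_used[1], 120L)

  # threshold drop below an already-larger accumulator prompts at once
  reports2 <- dplyr::bind_rows(
    morning_report(severe = TRUE, minute = 1),
    morning_report(minute = 8 * 60 + 100)  # mild rating at accumulated 100 > 60
  )
  res2 <- step_engine(stream, reports2, window)
  mins2 <- as.integer(format(res2$events$timestamp, "%H")) * 60 +
    as.integer(format(res2$events$timestamp, "%M"))
  expect_equal(mins2[1] - (8 * 60 - 1), 100)
  expect_equal(res2$events$threshold_used[1], 60L)
})

test_that("engine matches the brute-force per-minute oracle on random days", {
  set.seed(77)
  for (i in 1:150) {
    d <- random_day()
    inp <- day_inputs(d)
    ev <- run_participant(inp$stream, inp$reports, inp$window,
                          start_date = DAY0, end_date = DAY0)
    oracle <- oracle_engine_day(engine_steps(d), d$in_window,
                                d$report_min, d$report_high)
    got_idx <- as.integer((as.numeric(ev$timestamp) - as.numeric(inp$t0)) / 60) + 1L
    expect_identical(got_idx, oracle$idx)
    expect_identical(ev$threshold_used, oracle$threshold_used)
    expect_identical(ev$response_steps, as.integer(oracle$response_steps))
    expect_identical(ev$responded, oracle$responded)
    # invariants: prompts only inside the wake window; spacing >= threshold
    expect_true(all(d$in_window[got_idx]))
    if (length(got_idx) > 1) {
      expect_true(all(diff(got_idx) >= ev$threshold_used[-1]))
    }
  }
})

test_that("state after a day reflects the trailing unbroken sedentary run", {
  steps <- rep(0L, 1440)
  steps[20 * 60 - 45] <- 50L  # active minute 45 min before window close
  stream <- flat_day_stream(steps = steps)
  window <- wake_windows("P1", "08:00", "20:00")
  res <- step_engine(stream, morning_report(minute = 1), window)
  # window closes at 20:00; grid continues to 23:59 (out of window -> acc 0)
  expect_equal(res$state$sedentary_accumulator, 0L)
  expect_equal(res$state$active_threshold, 60L)

  # window open through midnight: the trailing run is still accumulating
  steps2 <- rep(0L, 1440)
  steps2[1397] <- 50L  # active at 23:16, then sedentary to 23:59
  window2 <- wake_windows("P1", "08:00", "00:00")
  res2 <- step_engine(flat_day_stream(steps = steps2),
                      morning_report(minute = 1), window2)
  expect_equal(res2$state$sedentary_accumulator, 43L)
})
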