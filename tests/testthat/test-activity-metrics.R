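make_stream <- function(minutes, steps, worn = TRUE, pid = "P1", date = DAY0) {
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  minute_stream(pid, t0 + (minutes - 1) * 60, steps, worn)
}

test_that("wear minutes count worn samples and drive the 8-hour filter", {
  s480 <- make_stream(1:480, 0L)
  expect_equal(daily_wear_minutes(s480), 480)
  s479 <- make_stream(1:480, 0L, worn = c(rep(TRUE, 479), FALSE))
  expect_equal(daily_wear_minutes(s479), 479)
  expect_equal(daily_wear_minutes(s480[0, ]), 0L)

  window <- wake_windows("P1", "00:00", "23:59")
  expect_true(summarize_day(s480, window = window)$included)
  expect_false(summarize_day(s479, window = window)$included)
})

test_that("bout extraction finds maximal sedentary runs split by activity and sleep", {
  window <- wake_windows("P1", "08:00", "20:00")
  # 30 sedentary, 1 active, 90 sedentary from window open
  steps <- c(rep(0L, 30), 50L, rep(0L, 90))
  st <- make_stream(480 + (1:121), steps)
  b <- extract_bouts(st, window, cfg = metrics_config(treat_missing_as_sedentary = FALSE))
  expect_equal(b$duration, c(30L, 90L))
  expect_equal(max(b$duration), 90)
  expect_equal(mean(b$duration), 60)

  # fully active day
  act <- make_stream(480 + (1:120), 100L)
  b2 <- extract_bouts(act, window, cfg = metrics_config(treat_missing_as_sedentary = FALSE))
  expect_equal(nrow(b2), 0)

  # 120 sedentary minutes with sleep covering window minutes 41-80
  t0 <- as.POSIXct(paste(DAY0, "00:00:00"), tz = "UTC")
  sl <- sleep_episodes("P1", t0 + (480 + 40) * 60, t0 + (480 + 80) * 60)
  sed <- make_stream(480 + (1:120), 0L)
  b3 <- extract_bouts(sed, window, sleep = sl,
                      cfg = metrics_config(treat_missing_as_sedentary = FALSE))
  expect_equal(b3$duration, c(40L, 40L))
})

test_that("missing minutes obey the treat-missing-as-sedentary policy", {
  window <- wake_windows("P1", "08:00", "20:00")
  # samples at window minutes 1-30 and 61-90, gap between
  st <- make_stream(480 + c(1:30, 61:90), 0L)
  b_true <- extract_bouts(st, window, cfg = metrics_config(treat_missing_as_sedentary = TRUE))
  expect_equal(b_true$duration, 720L)  # whole waking day sedentary
  b_false <- extract_bouts(st, window, cfg = metrics_config(treat_missing_as_sedentary = FALSE))
  expect_equal(b_false$duration, c(30L, 30L))
})

test_that("bout extractor matches the brute-force oracle and conserves minutes", {
  set.seed(99)
  for (i in 1:150) {
    d <- random_day()
    inp <- day_inputs(d)
    for (miss in c(TRUE, FALSE)) {
      cfg <- metrics_config(treat_missing_as_sedentary = miss)
      b <- extract_bouts(inp$stream, inp$window, inp$sleep, cfg)
      expect_identical(b$duration,
                       oracle_bout_durations(d$present, d$steps, d$in_window,
                                             d$asleep, treat_missing = miss))
      if (nrow(b) > 0) {
        expect_gte(max(b$duration), mean(b$duration))
        expect_gte(mean(b$duration), 1)
      }
    }
    # conservation: bout + active + sleep-excluded minutes fill the window
    cfg <- metrics_config(treat_missing_as_sedentary = TRUE)
    b <- extract_bouts(inp$stream, inp$window, inp$sleep, cfg)
    w <- d$in_window
    slept <- sum(w & d$asleep)
    active <- sum(w & !d$asleep & d$present & d$steps >= 10)
    expect_equal(sum(b$duration) + active + slept, sum(w))
  }
})

test_that("daily summary fields match an independent recomputation", {
  window <- wake_windows("P1", "08:00", "20:00")
  steps <- c(rep(0L, 200), rep(20L, 100), rep(0L, 420))
  st <- make_stream(480 + (1:720), steps)
  t0 <- as.POSIXct(paste(DAY0, "00:00:00"), tz = "UTC")
  sev <- stats::setNames(as.list(rep(1L, 10)), SYMPTOM_DIMENSIONS)
  rep1 <- symptom_reports("P1", t0 + 500 * 60, tibble::as_tibble(sev))
  ev <- tibble::tibble(participant_id = "P1",
                       timestamp = t0 + c(680, 740) * 60,
                       threshold_used = 60L,
                       responded = c(TRUE, FALSE),
                       response_steps = c(40L, 0L),
                       feedback_sent = c(TRUE, FALSE))
  s <- summarize_day(st, ev, rep1, window)
  expect_equal(s$wear_minutes, 720L)
  expect_equal(s$total_steps, 2000L)
  expect_equal(s$n_bouts, 2L)
  expect_equal(s$max_bout, 420)
  expect_equal(s$mean_bout, 310)
  expect_equal(s$n_prompts, 2L)
  expect_equal(s$n_responses, 1L)
  expect_true(s$symptom_reported)
  expect_true(s$included)

  # cross-day input is refused
  two_days <- dplyr::bind_rows(st, make_stream(1:10, 0L, date = DAY0 + 1))
  expect_error(summarize_day(two_days, window = window),
               class = "sedprompt_validation_error")
})

test_that("empty-bout days report zero max and mean", {
  window <- wake_windows("P1", "08:00", "20:00")
  act <- make_stream(480 + (1:720), 50L)
  s <- summarize_day(act, window = window)
  expect_equal(s$n_bouts, 0L)
  expect_equal(s$max_bout, 0)
  expect_equal(s$mean_bout, 0)
})

test_that("phase summaries pool response counts rather than averaging daily ratios", {
  mk <- function(n, prompts, responses, phase) {
    tibble::tibble(participant_id = "I01", arm = "intervention",
                   date = DAY0 + seq_len(n), phase = factor(phase, levels = PHASES),
                   wear_minutes = 600L, total_steps = 1000L, n_bouts = 1L,
                   max_bout = 100, mean_bout = 50,
                   n_prompts = prompts, n_responses = responses,
                   symptom_reported = TRUE, included = TRUE)
  }
  # 200/407 pooled = 49%, not the mean of per-day ratios
  d1 <- mk(2, c(7L, 400L), c(7L, 193L), "preoperative")
  p1 <- summarize_phase(d1)
  expect_equal(p1$response_fraction, 200 / 407)
  expect_equal(round_half_up(100 * p1$response_fraction), 49)
  expect_false(isTRUE(all.equal(p1$response_fraction, mean(c(1, 193 / 400)))))

  p2 <- summarize_phase(mk(2, c(400L, 62L), c(20L, 9L), "inpatient"))
  expect_equal(round_half_up(100 * p2$response_fraction), 6)

  p3 <- summarize_phase(mk(1, 2L, 1L, "postdischarge"))
  expect_equal(p3$response_fraction, 0.5)

  # zero prompts: undefined, flagged as NA rather than 0
  p0 <- summarize_phase(mk(3, 0L, 0L, "preoperative"))
  expect_true(is.na(p0$response_fraction))

  # pooled reconciliation across phases equals the overall summary
  all3 <- dplyr::bind_rows(d1, mk(2, c(400L, 62L), c(20L, 9L), "inpatient"),
                           mk(4, c(500L, 500L, 28L, 28L), c(60L, 60L, 35L, 34L), "postdischarge"))
  ph <- summarize_phase(all3)
  expect_equal(sum(ph$n_prompts), 1925L)
  expect_equal(sum(ph$n_responses), 418L)
  expect_equal(round_half_up(100 * sum(ph$n_responses) / sum(ph$n_prompts)), 22)
})

test_that("cohort daily summaries are day-independent and cover all study days", {
  set.seed(7)
  cfg <- cohort_config(n_per_arm = 1, seed = 301,
                       preop_days = dist_fixed(4), inpatient_days = dist_fixed(3),
                       postdischarge_days = 5)
  b <- simulate_cohort(cfg)
  daily <- summarize_days(b$stream, b$reports, b$events, b$sleep, b$participants)
  expect_equal(nrow(daily), 2 * (4 + 3 + 5))
  expect_equal(as.vector(table(daily$phase[daily$arm == "intervention"])), c(4, 3, 5))

  # dropping one day's samples leaves every other day's metrics unchanged
  drop_date <- b$participants$surgery_date[1]
  drop_pid <- b$participants$participant_id[1]
  thinned <- b$stream[!(b$stream$participant_id == drop_pid &
                          as.Date(b$stream$timestamp) == drop_date), ]
  daily2 <- summarize_days(thinned, b$reports, b$events, b$sleep, b$participants)
  keep <- !(daily$participant_id == drop_pid & daily$date == drop_date)
  expect_equal(daily2[keep, ], daily[keep, ])
  expect_equal(daily2$wear_minutes[!keep], 0L)
  expect_false(daily2$included[!keep])
})

test_that("adherence table reports printed-precision numerators and denominators", {
  n <- 1416L
  sym <- c(rep(TRUE, 874), rep(FALSE, n - 874))
  wear <- integer(n)
  wear[1:990] <- 600L                     # worn with >= 8 h
  wear[991:1091] <- 200L                  # worn, under 8 h
  daily <- tibble::tibble(
    participant_id = rep(c("A", "B"), length.out = n), arm = "intervention",
    date = DAY0 + seq_len(n), phase = factor("preoperative", levels = PHASES),
    wear_minutes = wear, total_steps = 0L, n_bouts = 0L, max_bout = 0,
    mean_bout = 0, n_prompts = 0L, n_responses = 0L,
    symptom_reported = sym, included = wear >= 480L
  )
  adh <- adherence_table(daily)
  expect_equal(adh$symptom_days$percent, 62)
  expect_equal(adh$symptom_days$numerator, 874L)
  expect_equal(adh$worn_days$percent, 77)
  expect_equal(adh$wear8h_among_worn$percent, 91)
  expect_equal(adh$wear8h_among_worn$numerator, 990L)
  expect_equal(adh$wear8h_among_worn$denominator, 1091L)

  zero <- daily; zero$symptom_reported <- FALSE
  expect_equal(adherence_table(zero)$symptom_days$percent, 0)
  expect_output(print(adh), "62%")
})
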