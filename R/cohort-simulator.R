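# Synthetic perioperative cohort generator.
#
# Minute-level activity is a two-state (sedentary/active) Markov chain within
# each waking day, per phase — the minimal structure that yields the
# geometric-tailed sedentary-run distributions the bout extractor must
# handle. Daily symptom reports, wear gaps, and naps are layered on top with
# phase-specific probabilities. For intervention-arm participants the
# prompting engine runs online during simulation: at every emitted prompt
# the simulated participant responds with the phase's response probability
# (injecting a 30-60-step walk over the next 3 minutes) or declines (staying
# still through the 15-minute response window), so intervention-arm behavior
# is prompt-contingent the way a just-in-time adaptive intervention assumes,
# and each prompt is an exact Bernoulli trial of the phase's response
# probability for parameter-recovery studies.

#' Distribution specification helpers
#'
#' `dist_uniform_int(min, max)` draws uniform integers; `dist_geom_int(min,
#' max, mean)` draws `min` plus a geometric count, redrawing values above
#' `max`, with the success probability solved so the truncated mean equals
#' `mean` (right-skewed durations whose printed mean sits well below the
#' range midpoint); `dist_fixed(value)` is degenerate.
#'
#' @param min,max integer bounds (inclusive).
#' @param mean target untruncated mean for the geometric form.
#' @param value fixed value.
#' @return A distribution spec list understood by [sample_dist()].
#' @export
dist_uniform_int <- function(min, max) {
  if (max < min) validation_error("dist_uniform_int: max < min")
  list(dist = "uniform_int", min = as.integer(min), max = as.integer(max))
}

#' @rdname dist_uniform_int
#' @export
dist_geom_int <- function(min, max, mean) {
  if (max < min) validation_error("dist_geom_int: max < min")
  if (mean <= min) validation_error("dist_geom_int: mean must exceed min")
  list(dist = "geom_int", min = as.integer(min), max = as.integer(max), mean = mean)
}

#' @rdname dist_uniform_int
#' @export
dist_fixed <- function(value) list(dist = "fixed", value = as.integer(value))

#' Draw from a distribution spec
#' @param spec a spec from [dist_uniform_int()], [dist_geom_int()] or [dist_fixed()].
#' @param n number of draws.
#' @return Integer vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1) {
  switch(spec$dist,
    uniform_int = spec$min + sample.int(spec$max - spec$min + 1L, n, replace = TRUE) - 1L,
    geom_int = {
      p <- geom_p_truncated(spec$mean - spec$min, spec$max - spec$min)
      x <- spec$min + stats::rgeom(n, p)
      while (any(bad <- x > spec$max)) x[bad] <- spec$min + stats::rgeom(sum(bad), p)
      as.integer(x)
    },
    fixed = rep(spec$value, n),
    validation_error("unknown distribution spec '%s'", spec$dist %||% "<missing>")
  )
}

# Geometric success probability whose mean, conditional on the draw not
# exceeding M, equals `target` (so right-truncation does not bias the
# phase-duration means away from the printed values).
#' @keywords internal
geom_p_truncated <- function(target, M) {
  if (target >= M) validation_error("geom_int mean too close to max for truncation")
  cond_mean <- function(p) {
    q <- 1 - p
    (q / p) - (M + 1) * q^(M + 1) / (1 - q^(M + 1))
  }
  stats::uniroot(function(p) cond_mean(p) - target,
                 interval = c(1e-8, 1 - 1e-8), tol = 1e-10)$root
}

#' @keywords internal
default_phase_params <- function() {
  list(
    preoperative = list(
      p_sed_to_active = 0.045, p_active_to_sed = 0.18, active_steps_mean = 32,
      sed_nonzero_p = 0.15, p_symptom_high = 0.15, p_report = 0.85,
      p_respond = 0.49, p_worn = 0.92, wear_mean = 800, wear_sd = 120,
      p_nap = 0.10
    ),
    inpatient = list(
      p_sed_to_active = 0.007, p_active_to_sed = 0.33, active_steps_mean = 25,
      sed_nonzero_p = 0.15, p_symptom_high = 0.70, p_report = 0.45,
      p_respond = 0.06, p_worn = 0.70, wear_mean = 650, wear_sd = 200,
      p_nap = 0.50
    ),
    postdischarge = list(
      p_sed_to_active = 0.028, p_active_to_sed = 0.16, active_steps_mean = 30,
      sed_nonzero_p = 0.15, p_symptom_high = 0.35, p_report = 0.55,
      p_respond = 0.18, p_worn = 0.72, wear_mean = 700, wear_sd = 180,
      p_nap = 0.25
    )
  )
}

#' Cohort simulator configuration
#'
#' All simulator parameters: arm sizes, phase-duration distributions
#' (preoperative mean 19.6 days within 8-47, inpatient mean 10.9 within
#' 5-24, 30 days post discharge), the shared wake window, engine settings,
#' and per-phase behavior parameters (Markov-chain transition probabilities,
#' step magnitudes, probability that any symptom is rated severe, daily
#' reporting probability, wear distribution, nap probability, and
#' prompt-response probability). Defaults sit in the neighborhoods of the
#' trial's printed phase statistics; see the methods vignette.
#'
#' @param n_per_arm participants per arm (13 echoes the trial).
#' @param seed integer seed; a fixed seed yields an identical cohort.
#' @param anchor_surgery_date Date of the first participant's surgery;
#'   subsequent participants are staggered 3 days apart.
#' @param preop_days,inpatient_days distribution specs for phase durations.
#' @param postdischarge_days days of follow-up after discharge.
#' @param wake_time,bed_time "HH:MM" wake window shared by the cohort.
#' @param engine an [engine_config()].
#' @param response_steps_min,response_steps_max range of total steps walked
#'   when a prompt is answered (>= the 30-step response goal).
#' @param phases per-phase parameter list; see [cohort_config()] defaults.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = 13L, seed = 1L,
                          anchor_surgery_date = as.Date("2023-03-01"),
                          preop_days = dist_geom_int(8, 47, 19.6),
                          inpatient_days = dist_geom_int(5, 24, 10.9),
                          postdischarge_days = 30L,
                          wake_time = "07:00", bed_time = "22:00",
                          engine = engine_config(),
                          response_steps_min = 30L, response_steps_max = 60L,
                          phases = default_phase_params()) {
  cfg <- list(n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
              anchor_surgery_date = as.Date(anchor_surgery_date),
              preop_days = preop_days, inpatient_days = inpatient_days,
              postdischarge_days = as.integer(postdischarge_days),
              wake_time = wake_time, bed_time = bed_time, engine = engine,
              response_steps_min = as.integer(response_steps_min),
              response_steps_max = as.integer(response_steps_max),
              phases = phases)
  if (cfg$n_per_arm < 1) validation_error("n_per_arm must be >= 1")
  if (cfg$postdischarge_days < 1) validation_error("postdischarge_days must be >= 1")
  if (cfg$response_steps_min < engine$response_step_goal) {
    validation_error("response_steps_min below the %d-step response goal", engine$response_step_goal)
  }
  if (cfg$response_steps_max < cfg$response_steps_min) {
    validation_error("response_steps_max < response_steps_min")
  }
  parse_tod(c(wake_time, bed_time))
  for (ph in PHASES) {
    p <- cfg$phases[[ph]]
    if (is.null(p)) validation_error("phases must include '%s'", ph)
    for (f in c("p_sed_to_active", "p_active_to_sed", "p_symptom_high",
                "p_report", "p_respond", "p_worn", "p_nap", "sed_nonzero_p")) {
      v <- p[[f]]
      if (is.null(v) || is.na(v) || v < 0 || v > 1) {
        validation_error("phases$%s$%s must be a probability in [0, 1]", ph, f)
      }
    }
    if ((p$active_steps_mean %||% 0) < engine$sedentary_step_cut) {
      validation_error("phases$%s$active_steps_mean must be >= the sedentary step cut", ph)
    }
  }
  structure(cfg, class = "cohort_config")
}

# One waking day of the two-state chain; starts sedentary. Returns integer
# steps for `w` minutes.
#' @keywords internal
sim_chain_day <- function(w, p) {
  lens <- integer(0)
  states <- logical(0)
  while (sum(lens) < w) {
    k <- 16L
    # a zero transition probability is an absorbing state: cap at day length
    sl <- if (p$p_sed_to_active <= 0) rep(w, k) else stats::rgeom(k, p$p_sed_to_active) + 1L
    al <- if (p$p_active_to_sed <= 0) rep(w, k) else stats::rgeom(k, p$p_active_to_sed) + 1L
    lens <- c(lens, as.vector(rbind(sl, al)))
    states <- c(states, rep(c(TRUE, FALSE), k))
  }
  state <- rep(states, lens)[seq_len(w)]
  steps <- integer(w)
  nsed <- sum(state)
  if (nsed > 0) {
    steps[state] <- as.integer(stats::rbinom(nsed, 1, p$sed_nonzero_p) *
                                 sample.int(4L, nsed, replace = TRUE))
  }
  nact <- w - nsed
  if (nact > 0) {
    steps[!state] <- 10L + stats::rpois(nact, p$active_steps_mean - 10)
  }
  steps
}

#' Simulate one perioperative participant
#'
#' Draws phase durations, generates the minute-level activity chain, symptom
#' reports, naps and nightly sleep, and wear gaps; for the intervention arm
#' the prompting engine runs online so post-prompt behavior (walk or keep
#' sitting) is injected into the stream as it would unfold in the field.
#' Uses the current RNG state; seed upstream for determinism.
#'
#' @param cfg a [cohort_config()].
#' @param arm "intervention" or "monitoring".
#' @param participant_id identifier string.
#' @param surgery_date Date of surgery.
#' @return List with `participant` (one-row tibble), `stream`, `reports`,
#'   `sleep`, `events` (empty for monitoring arm).
#' @export
simulate_participant <- function(cfg, arm, participant_id,
                                 surgery_date = cfg$anchor_surgery_date) {
  ecfg <- cfg$engine
  n_pre <- sample_dist(cfg$preop_days, 1)
  n_in <- sample_dist(cfg$inpatient_days, 1)
  study_start <- surgery_date - n_pre
  discharge <- surgery_date + n_in - 1L
  study_end <- discharge + cfg$postdischarge_days

  windows <- wake_windows(participant_id, cfg$wake_time, cfg$bed_time)
  grid <- build_grid(participant_id, study_start, study_end, windows)
  n <- grid$n
  dates <- seq(study_start, study_end, by = "day")
  phase_of_day <- assign_phase(dates, surgery_date, discharge)
  wake <- windows$wake_min[1]
  wlen <- (windows$bed_min[1] - wake) %% 1440L

  steps <- integer(n)
  worn <- logical(n)
  sleep_start <- list()
  sleep_end <- list()
  rep_time <- list()
  rep_high <- logical(0)

  for (d in seq_along(dates)) {
    p <- cfg$phases[[as.character(phase_of_day[d])]]
    off <- (d - 1L) * 1440L
    widx <- off + wake + seq_len(wlen)
    widx <- widx[widx <= n]
    steps[widx] <- sim_chain_day(length(widx), p)

    # daytime nap
    if (stats::runif(1) < p$p_nap) {
      nap_len <- sample(30:90, 1)
      nap_off <- sample.int(max(1L, wlen - nap_len), 1)
      nidx <- off + wake + nap_off + seq_len(nap_len) - 1L
      nidx <- nidx[nidx <= n]
      steps[nidx] <- 0L
      sleep_start[[length(sleep_start) + 1L]] <- grid$t0 + (nidx[1] - 1) * MINUTE
      sleep_end[[length(sleep_end) + 1L]] <- grid$t0 + nidx[length(nidx)] * MINUTE
    }
    # nightly sleep episode (outside the wake window)
    night_s <- off + wake + wlen + 30L
    night_e <- min(off + 1440L + wake - 30L, n)
    if (night_s < night_e) {
      sleep_start[[length(sleep_start) + 1L]] <- grid$t0 + (night_s - 1) * MINUTE
      sleep_end[[length(sleep_end) + 1L]] <- grid$t0 + night_e * MINUTE
    }

    # wear block starting at wake
    if (stats::runif(1) < p$p_worn) {
      wmin <- as.integer(round(stats::rnorm(1, p$wear_mean, p$wear_sd)))
      wmin <- max(60L, min(wmin, 1440L - wake))
      bidx <- off + wake + seq_len(wmin)
      worn[bidx[bidx <= n]] <- TRUE
    }

    # morning symptom report
    if (stats::runif(1) < p$p_report) {
      rt <- grid$t0 + (off + wake + sample(30:120, 1)) * MINUTE
      high <- stats::runif(1) < p$p_symptom_high
      rep_time[[length(rep_time) + 1L]] <- rt
      rep_high <- c(rep_high, high)
    }
  }
  steps[!worn] <- 0L

  reports <- NULL
  if (length(rep_time) > 0) {
    nr <- length(rep_time)
    sev <- matrix(sample(0:4, nr * 10L, replace = TRUE), nrow = nr,
                  dimnames = list(NULL, SYMPTOM_DIMENSIONS))
    # one designated dimension carries the severe/not-severe mixture so the
    # any-severity>=7 indicator is exactly Bernoulli(p_symptom_high)
    sev[, "fatigue"] <- ifelse(rep_high,
                               sample(7:10, nr, replace = TRUE),
                               sample(0:6, nr, replace = TRUE))
    reports <- symptom_reports(rep(participant_id, nr),
                               do.call(c, rep_time), tibble::as_tibble(sev))
  }

  events <- empty_events()
  if (identical(arm, "intervention")) {
    thr <- threshold_series(n, grid$t0, reports, ecfg)
    day_of_idx <- function(m) dates[(m - 1L) %/% 1440L + 1L]
    respond_cb <- function(m, thr_used) {
      p <- cfg$phases[[as.character(assign_phase(day_of_idx(m), surgery_date, discharge))]]
      if (stats::runif(1) < p$p_respond) {
        total <- sample(cfg$response_steps_min:cfg$response_steps_max, 1)
        third <- total %/% 3L
        walk <- c(third, third, total - 2L * third)
        idx <- m + 1:3
        keep <- idx <= n
        worn[idx[keep]] <<- TRUE
        list(idx = idx[keep], steps = walk[keep])
      } else {
        idx <- m + seq_len(ecfg$response_window)
        idx <- idx[idx <= n]
        list(idx = idx, steps = rep(0L, length(idx)))
      }
    }
    core <- run_engine_core(steps, thr, grid$in_window, ecfg, respond_cb)
    steps <- core$steps
    events <- events_tibble(participant_id, grid, core)
  }

  keep <- worn
  stream <- tibble::tibble(
    participant_id = rep(participant_id, sum(keep)),
    timestamp = grid$time[keep],
    steps = steps[keep],
    worn = TRUE
  )
  sleep <- if (length(sleep_start) > 0) {
    sleep_episodes(rep(participant_id, length(sleep_start)),
                   do.call(c, sleep_start), do.call(c, sleep_end))
  } else {
    tibble::tibble(participant_id = character(0),
                   start = as.POSIXct(character(0), tz = "UTC"),
                   end = as.POSIXct(character(0), tz = "UTC"))
  }
  participant <- tibble::tibble(
    participant_id = participant_id, arm = arm,
    surgery_date = surgery_date, discharge_date = discharge,
    wake_time = cfg$wake_time, bed_time = cfg$bed_time,
    study_start = study_start, study_end = study_end
  )
  list(participant = participant, stream = stream,
       reports = reports %||% empty_reports(), sleep = sleep, events = events)
}

#' @keywords internal
empty_reports <- function() {
  sev <- stats::setNames(rep(list(integer(0)), 10), SYMPTOM_DIMENSIONS)
  dplyr::bind_cols(tibble::tibble(participant_id = character(0),
                                  timestamp = as.POSIXct(character(0), tz = "UTC")),
                   tibble::as_tibble(sev))
}

#' Simulate a full perioperative cohort
#'
#' `n_per_arm` participants per arm, all streams concatenated, plus a
#' manifest recording the seed and every ground-truth parameter. With a
#' fixed seed the bundle is identical across runs.
#'
#' @param cfg a [cohort_config()].
#' @return List of class `sedprompt_bundle` with elements `participants`,
#'   `stream`, `reports`, `sleep`, `events`, `manifest`, `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  if (!inherits(cfg, "cohort_config")) cfg <- do.call(cohort_config, cfg)
  set.seed(cfg$seed)
  sims <- vector("list", 2L * cfg$n_per_arm)
  k <- 0L
  for (arm in c("intervention", "monitoring")) {
    for (i in seq_len(cfg$n_per_arm)) {
      k <- k + 1L
      pid <- sprintf("%s%02d", if (arm == "intervention") "I" else "M", i)
      sims[[k]] <- simulate_participant(cfg, arm, pid,
                                        cfg$anchor_surgery_date + (k - 1L) * 3L)
    }
  }
  participants <- dplyr::bind_rows(lapply(sims, `[[`, "participant"))
  manifest <- list(
    package = "sedprompt",
    seed = cfg$seed,
    n_per_arm = cfg$n_per_arm,
    wake_time = cfg$wake_time, bed_time = cfg$bed_time,
    postdischarge_days = cfg$postdischarge_days,
    preop_days = cfg$preop_days, inpatient_days = cfg$inpatient_days,
    engine = unclass(cfg$engine),
    response_steps_min = cfg$response_steps_min,
    response_steps_max = cfg$response_steps_max,
    phases = cfg$phases,
    participants = lapply(seq_len(nrow(participants)), function(i) {
      p <- participants[i, ]
      list(participant_id = p$participant_id, arm = p$arm,
           surgery_date = as.character(p$surgery_date),
           discharge_date = as.character(p$discharge_date),
           study_start = as.character(p$study_start),
           study_end = as.character(p$study_end))
    })
  )
  structure(list(
    participants = participants,
    stream = dplyr::bind_rows(lapply(sims, `[[`, "stream")),
    reports = dplyr::bind_rows(lapply(sims, `[[`, "reports")),
    sleep = dplyr::bind_rows(lapply(sims, `[[`, "sleep")),
    events = dplyr::bind_rows(lapply(sims, `[[`, "events")),
    manifest = manifest,
    config = cfg
  ), class = "sedprompt_bundle")
}

#' Write a cohort bundle to a directory
#'
#' Emits `minutes.csv`, `symptoms.csv`, `sleep.csv`, `events.csv`,
#' `participants.yaml`, and `manifest.json`.
#'
#' @param bundle a `sedprompt_bundle` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_minute_stream(bundle$stream, file.path(dir, "minutes.csv"))
  write_symptom_reports(bundle$reports, file.path(dir, "symptoms.csv"))
  write_sleep_episodes(bundle$sleep, file.path(dir, "sleep.csv"))
  write_events(bundle$events, file.path(dir, "events.csv"),
               bundle$manifest$engine$response_step_goal)
  write_participants(bundle$participants, file.path(dir, "participants.yaml"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort bundle from a directory
#' @param dir directory written by [write_bundle()] (a manifest is required).
#' @return A `sedprompt_bundle` list.
#' @export
read_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) validation_error("missing manifest.json in %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  goal <- manifest$engine$response_step_goal %||% 30L
  ev_path <- file.path(dir, "events.csv")
  structure(list(
    participants = read_participants(file.path(dir, "participants.yaml")),
    stream = read_minute_stream(file.path(dir, "minutes.csv")),
    reports = read_symptom_reports(file.path(dir, "symptoms.csv")),
    sleep = read_sleep_episodes(file.path(dir, "sleep.csv")),
    events = if (file.exists(ev_path)) read_events(ev_path, goal) else NULL,
    manifest = manifest,
    config = NULL
  ), class = "sedprompt_bundle")
}

#' @keywords internal
engine_config_from_manifest <- function(manifest) {
  e <- manifest$engine
  engine_config(e$sedentary_step_cut, e$low_threshold, e$high_threshold,
                e$severity_cut, e$response_window, e$response_step_goal,
                e$default_threshold_when_unrated, e$prompt_text, e$feedback_text)
}

#' Parameter recovery on a simulated bundle
#'
#' Re-runs the prompting engine and metrics over a bundle and compares, per
#' phase, the empirical prompt-response fraction, the fraction of reports
#' with any severity at or above the cut, and daily report adherence against
#' the manifest's configured probabilities, each with an exact (Clopper-
#' Pearson) 95% binomial interval and a pass flag (configured value inside
#' the interval).
#'
#' @param bundle a `sedprompt_bundle` or a directory path.
#' @param conf_level interval confidence level.
#' @return Tibble: phase, parameter, configured, estimate, n, ci_lo, ci_hi, pass.
#' @export
recover_parameters <- function(bundle, conf_level = 0.95) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  manifest <- bundle$manifest
  if (is.null(manifest)) validation_error("bundle has no manifest")
  ecfg <- engine_config_from_manifest(manifest)
  participants <- bundle$participants
  events <- replay_engine(bundle, ecfg)
  daily <- summarize_days(bundle$stream, bundle$reports, events, bundle$sleep,
                          participants, metrics_config(),
                          sedentary_step_cut = ecfg$sedentary_step_cut)
  idaily <- daily[daily$arm == "intervention", , drop = FALSE]

  high_cut <- ecfg$severity_cut
  rp <- bundle$reports
  sev_any <- if (nrow(rp) > 0) {
    apply(as.matrix(rp[SYMPTOM_DIMENSIONS]) >= high_cut, 1, any)
  } else {
    logical(0)
  }
  pmap <- stats::setNames(participants$surgery_date, participants$participant_id)
  dmap <- stats::setNames(participants$discharge_date, participants$participant_id)
  rp_phase <- if (nrow(rp) > 0) {
    assign_phase(rp$timestamp, pmap[rp$participant_id], dmap[rp$participant_id])
  } else {
    factor(character(0), levels = PHASES)
  }

  rows <- list()
  for (ph in PHASES) {
    cfg_ph <- manifest$phases[[ph]]
    di <- idaily[idaily$phase == ph, , drop = FALSE]
    rows[[length(rows) + 1L]] <- recovery_row(
      ph, "p_respond", cfg_ph$p_respond,
      sum(di$n_responses), sum(di$n_prompts), conf_level)
    keep <- rp_phase == ph
    rows[[length(rows) + 1L]] <- recovery_row(
      ph, "p_symptom_high", cfg_ph$p_symptom_high,
      sum(sev_any[keep]), sum(keep), conf_level)
    dall <- daily[daily$phase == ph, , drop = FALSE]
    rows[[length(rows) + 1L]] <- recovery_row(
      ph, "p_report", cfg_ph$p_report,
      sum(dall$symptom_reported), nrow(dall), conf_level)
  }
  dplyr::bind_rows(rows)
}

#' @keywords internal
recovery_row <- function(phase, parameter, configured, x, n, conf_level) {
  if (n > 0) {
    ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
    est <- x / n
  } else {
    ci <- c(NA_real_, NA_real_)
    est <- NA_real_
  }
  tibble::tibble(phase = phase, parameter = parameter,
                 configured = configured, estimate = est, n = as.integer(n),
                 ci_lo = ci[1], ci_hi = ci[2],
                 pass = !is.na(est) & configured >= ci[1] & configured <= ci[2])
}

# Deterministic offline engine replay over a bundle's intervention arm.
#' @keywords internal
replay_engine <- function(bundle, ecfg) {
  participants <- bundle$participants
  windows <- wake_windows(participants$participant_id, participants$wake_time,
                          participants$bed_time)
  out <- list()
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    if (p$arm != "intervention") next
    st <- bundle$stream[bundle$stream$participant_id == p$participant_id, , drop = FALSE]
    if (nrow(st) == 0) next
    rp <- bundle$reports[bundle$reports$participant_id == p$participant_id, , drop = FALSE]
    out[[length(out) + 1L]] <- run_participant(
      st, rp, windows, ecfg, arm = "intervention",
      start_date = p$study_start, end_date = p$study_end)
  }
  if (length(out) == 0) return(empty_events())
  dplyr::bind_rows(out)
}
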