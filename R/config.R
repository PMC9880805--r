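#' Symptom dimensions rated daily
#'
#' The ten symptom severities collected once per morning, each on a 0 (not
#' present) to 10 (as bad as you can imagine) numeric rating scale. Column
#' names used throughout the package for symptom-report tables.
#'
#' @format Character vector of length 10.
#' @export
SYMPTOM_DIMENSIONS <- c("pain", "fatigue", "sleep", "concentration", "sadness",
                        "anxiety", "dyspnea", "numbness", "nausea", "bowel")

#' Prompting engine configuration
#'
#' Parameters of the sedentary-behavior prompting rule. A minute with fewer
#' than `sedentary_step_cut` steps counts as sedentary. A prompt fires when
#' `low_threshold` consecutive sedentary minutes accumulate while all ten
#' symptoms in the most recent daily rating are below `severity_cut`, or
#' `high_threshold` consecutive sedentary minutes when any symptom was rated
#' at `severity_cut` or higher (fewer prompts on high-symptom days). A prompt
#' is answered when at least `response_step_goal` steps are logged within
#' `response_window` minutes after it, which triggers the positive feedback
#' message.
#'
#' @param sedentary_step_cut steps/min below which a minute is sedentary (10).
#' @param low_threshold prompt threshold, minutes, when all symptoms are mild (60).
#' @param high_threshold prompt threshold, minutes, when any symptom is severe (120).
#' @param severity_cut symptom severity (0-10) at or above which the high
#'   threshold applies (7).
#' @param response_window minutes after a prompt in which steps count as a
#'   response (15).
#' @param response_step_goal steps required within the response window (30).
#' @param default_threshold_when_unrated threshold, minutes, used before any
#'   symptom report exists (120: conservative, fewer prompts when patient
#'   state is unknown).
#' @param prompt_text,feedback_text notification message strings echoed into
#'   event logs.
#' @return A list of class `engine_config`.
#' @examples
#' cfg <- engine_config()
#' cfg$low_threshold
#' @export
engine_config <- function(sedentary_step_cut = 10L,
                          low_threshold = 60L,
                          high_threshold = 120L,
                          severity_cut = 7L,
                          response_window = 15L,
                          response_step_goal = 30L,
                          default_threshold_when_unrated = 120L,
                          prompt_text = "Ready for a short walk?",
                          feedback_text = "Great job being active!") {
  cfg <- list(
    sedentary_step_cut = as.integer(sedentary_step_cut),
    low_threshold = as.integer(low_threshold),
    high_threshold = as.integer(high_threshold),
    severity_cut = as.integer(severity_cut),
    response_window = as.integer(response_window),
    response_step_goal = as.integer(response_step_goal),
    default_threshold_when_unrated = as.integer(default_threshold_when_unrated),
    prompt_text = as.character(prompt_text),
    feedback_text = as.character(feedback_text)
  )
  if (cfg$sedentary_step_cut < 1) validation_error("sedentary_step_cut must be >= 1")
  if (!(cfg$low_threshold > 0 && cfg$low_threshold <= cfg$high_threshold)) {
    validation_error("need 0 < low_threshold <= high_threshold, got %d and %d",
                     cfg$low_threshold, cfg$high_threshold)
  }
  if (cfg$response_window < 1) validation_error("response_window must be >= 1")
  if (cfg$severity_cut < 1 || cfg$severity_cut > 10) {
    validation_error("severity_cut must be in [1, 10], got %d", cfg$severity_cut)
  }
  if (!cfg$default_threshold_when_unrated %in% c(cfg$low_threshold, cfg$high_threshold)) {
    validation_error("default_threshold_when_unrated must equal low_threshold or high_threshold")
  }
  if (cfg$response_step_goal < 1) validation_error("response_step_goal must be >= 1")
  structure(cfg, class = "engine_config")
}

#' Activity-metrics configuration
#'
#' @param min_wear_minutes minimum worn minutes for a day to enter activity
#'   analyses (480 = 8 h; wear need not be consecutive).
#' @param treat_missing_as_sedentary if `TRUE` (default) minutes with no
#'   recorded sample count as sedentary when finding bouts, mirroring a
#'   wrist device that logs zero steps while idle or off wrist; if `FALSE`
#'   missing minutes break sedentary runs.
#' @param exclude_sleep if `TRUE` (default) minutes inside device-detected
#'   sleep episodes are removed before sedentary runs are found, splitting
#'   runs at episode boundaries.
#' @return A list of class `metrics_config`.
#' @export
metrics_config <- function(min_wear_minutes = 480L,
                           treat_missing_as_sedentary = TRUE,
                           exclude_sleep = TRUE) {
  min_wear_minutes <- as.integer(min_wear_minutes)
  if (is.na(min_wear_minutes) || min_wear_minutes < 1 || min_wear_minutes > 1440) {
    validation_error("min_wear_minutes must be in [1, 1440]")
  }
  structure(list(
    min_wear_minutes = min_wear_minutes,
    treat_missing_as_sedentary = isTRUE(treat_missing_as_sedentary),
    exclude_sleep = isTRUE(exclude_sleep)
  ), class = "metrics_config")
}
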