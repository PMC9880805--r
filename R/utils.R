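# Internal helpers shared across modules.

MINUTE <- 60L

#' @keywords internal
validation_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = c("sedprompt_validation_error", "sedprompt_error"))
}

#' @keywords internal
parse_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = c("sedprompt_parse_error", "sedprompt_error"))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in clinical
#' reports conventionally round half away from zero (0.5 -> 1).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(-0.5)  # -1
#' round_half_up(2.45, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Timestamps are minute-granular, timezone-naive local time; represented as
# POSIXct in UTC so arithmetic never crosses DST boundaries.
#' @keywords internal
parse_minute_ts <- function(x) {
  x <- as.character(x)
  x2 <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x2, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    parse_error("unparseable timestamp '%s' (row %d)", x[bad[1]], bad[1])
  }
  floor_minute(out)
}

#' @keywords internal
floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / MINUTE) * MINUTE,
             origin = "1970-01-01", tz = "UTC")
}

#' @keywords internal
format_minute_ts <- function(t) {
  format(t, "%Y-%m-%dT%H:%M", tz = "UTC")
}

#' @keywords internal
ts_date <- function(t) {
  as.Date(t, tz = "UTC")
}

# "HH:MM" time-of-day -> integer minutes since midnight
#' @keywords internal
parse_tod <- function(x) {
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
  if (any(!ok)) {
    validation_error("invalid time-of-day '%s' (expected HH:MM)", x[!ok][1])
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]), integer(1))
}

#' @keywords internal
format_tod <- function(mins) {
  sprintf("%02d:%02d", mins %/% 60L, mins %% 60L)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
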