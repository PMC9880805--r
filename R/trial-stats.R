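# Small-sample trial statistics applied to fixed tables: proportions with
# printed-precision rounding, Pearson chi-square on 2x2 tables, and
# two-sample t tests reconstructed from group summary statistics.

#' Proportion with printed-precision percentage
#'
#' @param numerator,denominator non-negative integers, numerator <= denominator,
#'   denominator >= 1.
#' @return List with `fraction` and `percent` (rounded half away from zero
#'   to an integer, the convention used when printing trial percentages).
#' @examples
#' proportion_pct(26, 35)   # 74% accrual
#' proportion_pct(418, 1925)  # 22% of prompts followed by walking
#' @export
proportion_pct <- function(numerator, denominator) {
  if (!is_count(numerator) || !is_count(denominator)) {
    validation_error("numerator and denominator must be non-negative integers")
  }
  if (denominator < 1) validation_error("denominator must be >= 1")
  if (numerator > denominator) validation_error("numerator exceeds denominator")
  frac <- numerator / denominator
  list(fraction = frac, percent = round_half_up(100 * frac))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson statistic `n (ad - bc)^2 / (r1 r2 c1 c2)` with 1
#' degree of freedom and a two-sided p value from the chi-square
#' distribution. Continuity (Yates) correction is off by default; it is the
#' uncorrected statistic that standard trial reports print for arm-by-outcome
#' tables of this size.
#'
#' @param a,b,c,d cell counts; rows are study arms, columns outcomes.
#' @param correct apply the Yates continuity correction.
#' @return List with `statistic`, `df`, `p`, and the `table` used.
#' @examples
#' pearson_chi2(5, 7, 4, 8)  # readmitted vs not, by arm
#' @export
pearson_chi2 <- function(a, b, c, d, correct = FALSE) {
  cells <- c(a, b, c, d)
  if (!all(vapply(cells, is_count, logical(1)))) {
    validation_error("cell counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n < 1) validation_error("grand total must be >= 1")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    validation_error("chi-square statistic undefined: a row or column margin is zero")
  }
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
}

#' Two-sample t test from group summary statistics
#'
#' Independent two-tailed t test reconstructed from per-group n, mean, and
#' SD, as used for baseline and end-of-study usability comparisons. The
#' pooled-variance Student form (df = n1 + n2 - 2) is the default; the
#' Welch form is available via `pooled = FALSE`.
#'
#' @param n1,mean1,sd1 first group: size (>= 2), mean, SD (>= 0).
#' @param n2,mean2,sd2 second group.
#' @param pooled use pooled-variance Student t (default) or Welch.
#' @return List with `t`, `df`, and two-sided `p`.
#' @examples
#' two_sample_t_from_summary(9, 91.1, 8.3, 11, 94.6, 6.1)
#' @export
two_sample_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2, pooled = TRUE) {
  if (n1 < 2 || n2 < 2) validation_error("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) validation_error("sd must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    validation_error("t undefined: both SDs are zero with unequal means")
  }
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
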