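#' Consolidate repeat skinfold measurements (ISAK rule)
#'
#' Kinanthropometric practice takes two calliper measurements per site and
#' uses their mean, unless they differ by at least 5%, in which case a third
#' is taken and the median of the three is used. The relative difference is
#' `|m1 - m2| / mean(m1, m2)`.
#'
#' @param m1,m2 first and second measurements (mm, > 0).
#' @param m3 third measurement (mm); required iff the first two differ by
#'   >= 5%.
#' @return consolidated site value (mm).
#' @export
isak_value <- function(m1, m2, m3 = NULL) {
  if (m1 <= 0 || m2 <= 0) stopf("skinfold measures must be > 0 mm")
  rel <- abs(m1 - m2) / mean(c(m1, m2))
  if (rel < 0.05) return(mean(c(m1, m2)))
  if (is.null(m3))
    stopf("incomplete-measurement error: %.1f and %.1f differ by %.1f%% (>= 5%%); a third measure is required",
          m1, m2, 100 * rel)
  if (m3 <= 0) stopf("skinfold measures must be > 0 mm")
  stats::median(c(m1, m2, m3))
}

#' Four-site skinfold percentage body fat
#'
#' Sex-specific quadratic equations in the sum `S` of the abdominal, tricep,
#' front-thigh and iliac-crest skinfolds (mm) plus an age term:
#' \deqn{men: 0.29288 S - 0.0005 S^2 + 0.15845 age - 5.76377}
#' \deqn{women: 0.29669 S - 0.00043 S^2 + 0.02963 age + 1.4072}
#' Results outside `[0, 75]` percent are implausible for calliper data and
#' are returned with a warning rather than suppressed.
#'
#' @param sex `"male"` or `"female"`.
#' @param S sum of the four skinfolds (mm, > 0; the female constant is the
#'   `S = 0, age = 0` limit).
#' @param age age in years (> 0).
#' @return estimated percentage body fat.
#' @export
jackson_pollock_bodyfat <- function(sex = c("male", "female"), S, age) {
  sex <- match.arg(sex)
  if (any(S < 0)) stopf("sum of skinfolds must be >= 0 mm")
  if (any(age < 0)) stopf("age must be >= 0 years")
  pct <- if (sex == "male")
    0.29288 * S - 0.0005 * S^2 + 0.15845 * age - 5.76377
  else
    0.29669 * S - 0.00043 * S^2 + 0.02963 * age + 1.4072
  if (any(pct < 0 | pct > 75))
    warnf("implausible body fat estimate (%.1f%%) outside [0, 75]", pct)
  pct
}

#' Fat mass from percentage body fat and weight
#'
#' @param percent percentage body fat in `[0, 100]`.
#' @param weight total body weight (kg, > 0).
#' @return fat mass (kg).
#' @export
fat_mass_from_percent <- function(percent, weight) {
  if (any(percent < 0 | percent > 100))
    stopf("parameter error: percent must lie in [0, 100]")
  if (any(weight <= 0)) stopf("parameter error: weight must be > 0 kg")
  weight * percent / 100
}

#' Bland-Altman agreement between two measurement methods
#'
#' Differences `a - b` summarised by their mean and SD; the 95% limits of
#' agreement are mean +/- 1.96 SD. The Pearson correlation of the raw
#' measurements is reported alongside.
#'
#' @param a,b paired measurement vectors of equal length (>= 2).
#' @return object of class `agreement_stats` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pearson_r`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stopf("pairing error: lengths differ (%d vs %d)", length(a), length(b))
  if (length(a) < 2L) stopf("need at least 2 pairs")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 pearson_r = r, n = length(a)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats (n = %d): mean diff %.3f, LoA [%.3f, %.3f], r = %.3f>\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high, x$pearson_r))
  invisible(x)
}

#' Test-retest intraclass correlation coefficient
#'
#' Two-way, absolute-agreement, single-measurement ICC (ICC(A,1)) from the
#' standard mean-squares decomposition of the subjects x occasions table:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with k = 2 occasions. `variant = "consistency"` gives the two-way
#' consistency single-measure ICC instead.
#'
#' @param t1,t2 measurement vectors at the two occasions, equal length >= 3.
#' @param variant `"agreement"` (default) or `"consistency"`.
#' @return the ICC (in `[-1, 1]`); `NA` with a warning if the between-subject
#'   variance is zero.
#' @export
icc_agreement <- function(t1, t2, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  if (length(t1) != length(t2))
    stopf("pairing error: lengths differ (%d vs %d)", length(t1), length(t2))
  n <- length(t1)
  if (n < 3L) stopf("need at least 3 subjects")
  x <- cbind(t1, t2); k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1L)
  msc <- ssc / (k - 1L)
  mse <- sse / ((n - 1L) * (k - 1L))
  if (msr < .Machine$double.eps * max(1, abs(grand))) {
    warnf("degenerate data: zero between-subject variance, ICC undefined")
    return(NA_real_)
  }
  if (variant == "agreement")
    (msr - mse) / (msr + (k - 1L) * mse + (k / n) * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1L) * mse)
}
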