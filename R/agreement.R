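# Method-agreement statistics: paired and independent comparisons, effect
# sizes with Hopkins magnitude bands, validity (Pearson r, R^2, SEE),
# Bland-Altman limits of agreement with a proportional-bias slope, and the
# normality/homoscedasticity checks that gate the Welch/pooled choice.
#
# All formulas are written out explicitly (mean, SD, t-quantiles, OLS normal
# equations) so the test suite can check them against stats::t.test,
# stats::cor and stats::lm as independent oracles.

#' Paired comparison of two conditions
#'
#' Paired t-test of `x` against `y` with a paired Cohen's d. The default d
#' denominator is the mean of the two condition SDs, `(SD(x) + SD(y)) / 2`,
#' the convention used in repeated-trials fitness studies; the
#' change-score convention `SD(x - y)` is also available.
#'
#' @param x,y paired numeric vectors, equal length >= 3.
#' @param conf_level confidence level for the CI (default 0.95).
#' @param d_denominator `"mean_sd"` (default) or `"sd_diff"`.
#' @return list with `n`, `mean_diff` (mean of x - y), `ci` (length-2),
#'   `t`, `df`, `p`, `cohens_d`, `sd_diff`, and `degenerate` (TRUE when
#'   the differences have zero SD, in which case t/p/CI are NA).
#' @export
#' @examples
#' paired_comparison(c(1, 2, 3), c(1, 3, 5))
paired_comparison <- function(x, y, conf_level = 0.95,
                              d_denominator = c("mean_sd", "sd_diff")) {
  d_denominator <- match.arg(d_denominator)
  if (length(x) != length(y)) stop("'x' and 'y' must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  denom <- switch(d_denominator,
    mean_sd = (stats::sd(x) + stats::sd(y)) / 2,
    sd_diff = sdd)
  degenerate <- sdd == 0
  if (degenerate) {
    t <- p <- NA_real_
    ci <- c(md, md)
  } else {
    se <- sdd / sqrt(n)
    t <- md / se
    p <- 2 * stats::pt(-abs(t), df = n - 1)
    q <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
    ci <- md + c(-1, 1) * q * se
  }
  list(n = n, mean_diff = md, ci = ci, t = t, df = n - 1, p = p,
       cohens_d = if (denom > 0) md / denom else NA_real_,
       sd_diff = sdd, degenerate = degenerate)
}

#' Paired Cohen's d from summary statistics
#'
#' @param mean_diff mean of the paired differences.
#' @param sd1,sd2 SDs of the two conditions.
#' @return Cohen's d under the mean-of-SDs denominator.
#' @export
cohens_d_paired <- function(mean_diff, sd1, sd2) {
  mean_diff / ((sd1 + sd2) / 2)
}

#' Hedges' g from group summary statistics
#'
#' Absolute standardized mean difference with the small-sample correction
#' `J = 1 - 3 / (4 (n1 + n2) - 9)` applied to the pooled-SD (n - 1 weights)
#' effect.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return Hedges' g (non-negative).
#' @export
#' @examples
#' hedges_g(46.97, 5.07, 63, 49.69, 6.19, 67)  # 0.48
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  abs(mean1 - mean2) / sp * j
}

#' Independent two-group comparison
#'
#' Welch or pooled-variance t-test with Hedges' g. Under the default
#' `"auto"` policy a Levene check (center = mean) gates the choice: Welch
#' when variance equality is rejected at `levene_alpha`, pooled otherwise.
#'
#' @param a,b numeric vectors, each length >= 3.
#' @param variance `"auto"` (default), `"welch"` or `"pooled"`.
#' @param levene_alpha alpha for the variance-equality gate (default 0.05).
#' @return list with `t`, `df` (Welch-Satterthwaite when applicable), `p`,
#'   `hedges_g`, and `method` used.
#' @export
independent_comparison <- function(a, b,
                                   variance = c("auto", "welch", "pooled"),
                                   levene_alpha = 0.05) {
  variance <- match.arg(variance)
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, hedges_g = 0,
                  method = "degenerate"))
    }
    stop("both groups have zero variance", call. = FALSE)
  }
  if (variance == "auto") {
    lev <- assumption_checks(c(a, b), group = rep(1:2, c(n1, n2)))
    variance <- if (!is.na(lev$levene_p) && lev$levene_p < levene_alpha)
      "welch" else "pooled"
  }
  md <- mean(a) - mean(b)
  if (variance == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- md / se
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p,
       hedges_g = hedges_g(mean(a), stats::sd(a), n1,
                           mean(b), stats::sd(b), n2),
       method = variance)
}

#' Hopkins magnitude band for a standardized effect size
#'
#' Thresholds: <= 0.2 trivial; > 0.2 small; > 0.6 moderate; > 1.2 large;
#' > 2.0 very large; > 4.0 nearly perfect. The absolute value is taken.
#'
#' @param effect standardized effect size (d or g), vectorised.
#' @return character vector of band labels.
#' @export
#' @examples
#' hopkins_band(c(0.2, 0.48, 4.5))
hopkins_band <- function(effect) {
  e <- abs(effect)
  cut(e, breaks = c(-Inf, 0.2, 0.6, 1.2, 2.0, 4.0, Inf),
      labels = c("trivial", "small", "moderate", "large", "very large",
                 "nearly perfect"),
      right = TRUE) |> as.character()
}

#' Bland-Altman agreement analysis
#'
#' Differences `d_i = measured_i - predicted_i` against pairwise means
#' `m_i = (measured_i + predicted_i) / 2`. The limits of agreement are
#' `bias +/- k * SD(d)`; the proportional-bias slope is the OLS slope of d
#' on m (a slope far from 0 means the prediction compresses or stretches
#' the measured scale).
#'
#' @param measured,predicted paired numeric vectors, equal length >= 3.
#' @param k SD multiplier for the limits (default 1.96; 2.0 reproduces the
#'   "two standard deviations" description some studies use).
#' @return list with `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `ba_slope`, `ba_slope_p`, and `points` (data frame `mean`, `diff` for
#'   plotting).
#' @export
bland_altman <- function(measured, predicted, k = 1.96) {
  if (length(measured) != length(predicted)) {
    stop("'measured' and 'predicted' must be paired", call. = FALSE)
  }
  n <- length(measured)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- measured - predicted
  m <- (measured + predicted) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  if (stats::var(m) > 0) {
    slope <- sum((m - mean(m)) * (d - bias)) / sum((m - mean(m))^2)
    res <- d - bias - slope * (m - mean(m))
    if (n > 2 && sum(res^2) > 0) {
      se_slope <- sqrt(sum(res^2) / (n - 2) / sum((m - mean(m))^2))
      ts <- slope / se_slope
      slope_p <- 2 * stats::pt(-abs(ts), df = n - 2)
    } else {
      slope_p <- NA_real_
    }
  } else {
    slope <- 0
    slope_p <- NA_real_
  }
  list(bias = bias, sd_diff = sdd,
       loa_lower = bias - k * sdd, loa_upper = bias + k * sdd,
       ba_slope = slope, ba_slope_p = slope_p,
       points = data.frame(mean = m, diff = d))
}

#' Validity of a prediction: r, R^2 and the standard error of estimate
#'
#' Pearson correlation between measured and predicted values, its square,
#' and the SEE. The default SEE is the residual SD (n - 2 denominator) of
#' the OLS regression of measured on predicted; `see_method = "sdy"` gives
#' the shortcut `SD(measured) * sqrt(1 - r^2)` (n - 1 based) instead.
#'
#' @param measured,predicted paired numeric vectors, equal length >= 3,
#'   each with positive variance.
#' @param see_method `"residual"` (default) or `"sdy"`.
#' @return list with `r`, `r_squared`, `see`.
#' @export
validity_stats <- function(measured, predicted,
                           see_method = c("residual", "sdy")) {
  see_method <- match.arg(see_method)
  if (length(measured) != length(predicted)) {
    stop("'measured' and 'predicted' must be paired", call. = FALSE)
  }
  n <- length(measured)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::var(measured) == 0 || stats::var(predicted) == 0) {
    stop("zero variance in measured or predicted values", call. = FALSE)
  }
  xm <- predicted - mean(predicted)
  ym <- measured - mean(measured)
  r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  see <- switch(see_method,
    residual = {
      slope <- sum(xm * ym) / sum(xm^2)
      res <- ym - slope * xm
      sqrt(sum(res^2) / (n - 2))
    },
    sdy = stats::sd(measured) * sqrt(1 - r^2))
  list(r = r, r_squared = r^2, see = see)
}

#' Normality and homoscedasticity checks
#'
#' One-sample Kolmogorov-Smirnov test against a normal with the sample's
#' own mean and SD, and (when `group` is supplied) a Levene test with
#' center = mean across groups. Both are diagnostics: with estimated
#' parameters the plain KS p-value is conservative, so these gate the
#' Welch/pooled choice rather than support inference.
#'
#' @param x numeric vector, n >= 5.
#' @param group optional grouping factor for the Levene test.
#' @return list with `ks_stat`, `ks_p`, `levene_stat`, `levene_p` (the
#'   Levene entries are NA without a grouping).
#' @export
assumption_checks <- function(x, group = NULL) {
  if (length(x) < 5) stop("need n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant vector", call. = FALSE)
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
  lev_stat <- lev_p <- NA_real_
  if (!is.null(group)) {
    group <- as.factor(group)
    if (nlevels(group) >= 2) {
      z <- abs(x - stats::ave(x, group))
      a <- stats::anova(stats::lm(z ~ group))
      lev_stat <- a[["F value"]][1]
      lev_p <- a[["Pr(>F)"]][1]
    }
  }
  list(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       levene_stat = lev_stat, levene_p = lev_p)
}

#' Verdict for a prediction equation
#'
#' An equation is adequate when the paired test of measured against
#' predicted values is non-significant under strict `p < alpha`
#' significance, i.e. `p >= alpha` (so p exactly equal to alpha is
#' adequate).
#'
#' @param p_value p-value of the paired measured-vs-predicted test.
#' @param alpha significance level (default 0.05).
#' @return `"adequate"` or `"inadequate"`.
#' @export
classify_equation <- function(p_value, alpha = 0.05) {
  ifelse(is.na(p_value), NA_character_,
         ifelse(p_value >= alpha, "adequate", "inadequate"))
}
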