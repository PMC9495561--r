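# Direct-oximetry summaries and maximal-effort screening.
#
# VO2peak is defined as the highest 10-second average of the breath-by-
# breath VO2 signal. A trial counts as maximal when at least two of three
# physiological criteria are met (second ventilatory threshold exceeded;
# RER >= 1.0; HRpeak within 10 bpm of the Tanaka age-predicted maximum)
# AND the tester recorded subjective signs of exhaustion.

#' VO2peak from a breath-by-breath series
#'
#' Partitions time into consecutive 10-s bins anchored at the first sample
#' and returns the largest within-bin mean. Bins containing no samples are
#' skipped.
#'
#' @param time_s sample times in seconds, non-decreasing.
#' @param vo2 VO2 values in mL/kg/min, same length as `time_s`.
#' @param bin_s bin width in seconds (default 10).
#' @return VO2peak in mL/kg/min.
#' @export
#' @examples
#' vo2peak_from_breaths(seq(0, 59, 2), rep(40, 30))  # 40
vo2peak_from_breaths <- function(time_s, vo2, bin_s = 10) {
  if (length(time_s) == 0L || length(time_s) != length(vo2)) {
    stop("series must be non-empty with matching lengths", call. = FALSE)
  }
  if (is.unsorted(time_s)) {
    stop("'time_s' must be non-decreasing", call. = FALSE)
  }
  bin <- floor((time_s - time_s[1]) / bin_s)
  max(tapply(vo2, bin, mean))
}

#' Maximal-effort screening of one gas-exchange summary
#'
#' @param gas named list with `rer_max`, `hr_peak`, `vt2_exceeded`
#'   (logical) and `subjective_signs` (logical).
#' @param age years.
#' @param hr_rule `"one_sided"` (default) accepts any HRpeak at or above
#'   Tanaka minus 10 bpm — exceeding the age-predicted maximum cannot
#'   disqualify a maximal test; `"two_sided"` demands HRpeak within
#'   +/- 10 bpm of Tanaka.
#' @return list with `maximal` (logical), `n_physiological` (0-3) and
#'   `criteria`, a named logical breakdown (`vt2`, `rer`, `hr`,
#'   `subjective`).
#' @export
#' @examples
#' gas <- list(rer_max = 1.05, hr_peak = 195, vt2_exceeded = TRUE,
#'             subjective_signs = TRUE)
#' is_maximal_effort(gas, age = 7.6)$maximal  # TRUE
is_maximal_effort <- function(gas, age,
                              hr_rule = c("one_sided", "two_sided")) {
  hr_rule <- match.arg(hr_rule)
  gas <- as.list(gas)
  stopifnot(is.numeric(gas$rer_max), is.numeric(gas$hr_peak))
  hrmax <- tanaka_hrmax(age)
  hr_ok <- if (hr_rule == "one_sided") {
    gas$hr_peak >= hrmax - 10
  } else {
    abs(gas$hr_peak - hrmax) <= 10
  }
  crit <- c(
    vt2 = isTRUE(as.logical(gas$vt2_exceeded)),
    rer = gas$rer_max >= 1.0,
    hr = hr_ok,
    subjective = isTRUE(as.logical(gas$subjective_signs))
  )
  n_phys <- sum(crit[c("vt2", "rer", "hr")])
  list(maximal = n_phys >= 2 && crit[["subjective"]],
       n_physiological = n_phys,
       criteria = crit)
}

#' Screen a cohort for maximal effort
#'
#' Applies [is_maximal_effort()] to each child of a long-format cohort
#' (one row per child x condition, as produced by [generate_cohort()]);
#' gas-exchange fields are taken from the with-analyzer row.
#'
#' @param cohort cohort data frame.
#' @param hr_rule passed to [is_maximal_effort()].
#' @return data frame with one row per child: `child_id`, the four
#'   criterion flags, `n_physiological` and `included`.
#' @export
screen_cohort <- function(cohort, hr_rule = c("one_sided", "two_sided")) {
  hr_rule <- match.arg(hr_rule)
  gasrows <- cohort[cohort$condition == "with_analyzer", , drop = FALSE]
  res <- lapply(seq_len(nrow(gasrows)), function(i) {
    r <- gasrows[i, ]
    m <- is_maximal_effort(
      list(rer_max = r$rer, hr_peak = r$hr_peak,
           vt2_exceeded = r$vt2, subjective_signs = r$subjective),
      age = r$age_y, hr_rule = hr_rule)
    data.frame(child_id = r$child_id,
               vt2 = m$criteria[["vt2"]], rer = m$criteria[["rer"]],
               hr = m$criteria[["hr"]],
               subjective = m$criteria[["subjective"]],
               n_physiological = m$n_physiological,
               included = m$maximal)
  })
  do.call(rbind, res)
}

#' Read a breath-by-breath CSV (time_s, vo2_mlkgmin)
#'
#' @param path CSV path with columns `time_s` and `vo2_mlkgmin`.
#' @return data frame.
#' @export
read_breaths <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "vo2_mlkgmin") %in% names(d))) {
    stop("expected columns time_s, vo2_mlkgmin", call. = FALSE)
  }
  d
}
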