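# End-to-end study pipeline: screen a cohort for maximal effort, predict
# VO2peak with all 22 equations under both trial conditions, and run the
# agreement statistics per equation, condition and group.

#' Study configuration
#'
#' One object carries every analysis choice so a study run is reproducible
#' from cohort + config alone.
#'
#' @param alpha significance level; significance is strict `p < alpha`.
#' @param loa_k Bland-Altman limits-of-agreement SD multiplier.
#' @param variance `"auto"`, `"welch"` or `"pooled"` for independent
#'   comparisons (see [independent_comparison()]).
#' @param d_denominator paired Cohen's d denominator
#'   (see [paired_comparison()]).
#' @param profile equation evaluation profile (see [evaluate_equation()]).
#' @param fat_adjust when TRUE, measured-minus-predicted differences are
#'   adjusted for percent body fat (regressed on fat percent and evaluated
#'   at the group's mean fat percent) before the paired test. Off by
#'   default: the printed group means reproduce without it.
#' @param hr_rule maximal-effort heart-rate rule (see
#'   [is_maximal_effort()]).
#' @param see_method SEE definition (see [validity_stats()]).
#' @param round_digits decimals for table-style rounding in writers.
#' @return a named list of class `study_config`.
#' @export
study_config <- function(alpha = 0.05, loa_k = 1.96,
                         variance = c("auto", "welch", "pooled"),
                         d_denominator = c("mean_sd", "sd_diff"),
                         profile = c("table4", "as_printed"),
                         fat_adjust = FALSE,
                         hr_rule = c("one_sided", "two_sided"),
                         see_method = c("residual", "sdy"),
                         round_digits = 2) {
  structure(list(
    alpha = alpha, loa_k = loa_k,
    variance = match.arg(variance),
    d_denominator = match.arg(d_denominator),
    profile = match.arg(profile),
    fat_adjust = isTRUE(fat_adjust),
    hr_rule = match.arg(hr_rule),
    see_method = match.arg(see_method),
    round_digits = round_digits
  ), class = "study_config")
}

#' Run the full validity study on a cohort
#'
#' Screens trials for maximal effort, evaluates the 22 prediction
#' equations on both conditions, and computes the agreement statistics:
#' a cohort summary, the paired with/without-analyzer performance
#' comparison, per-equation prediction summaries with sex and condition
#' comparisons, per-equation measured-vs-predicted difference tests with
#' verdicts, and Bland-Altman/validity statistics for the equations judged
#' adequate. Deterministic given cohort and config.
#'
#' @param cohort a cohort data frame (from [generate_cohort()] or
#'   [read_cohort()]) or a path to a cohort CSV.
#' @param config a [study_config()].
#' @return list of class `study_report` with elements `screening`,
#'   `cohort_summary`, `condition_comparison`, `predictions`,
#'   `prediction_summary`, `difference_tests`, `bland_altman`, `verdicts`,
#'   `config`.
#' @export
run_study <- function(cohort, config = study_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(config, "study_config"))
  need <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(need)) {
    stop("cohort lacks columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cohort$sex <- match_sex(cohort$sex)

  screening <- screen_cohort(cohort, hr_rule = config$hr_rule)
  keep <- screening$child_id[screening$included]
  if (!length(keep)) stop("all children excluded by effort screening",
                          call. = FALSE)
  coh <- cohort[cohort$child_id %in% keep, , drop = FALSE]
  for (sx in c("girl", "boy")) {
    if (length(unique(coh$child_id[coh$sex == sx])) < 3) {
      stop("need at least 3 included children per sex", call. = FALSE)
    }
  }

  groups <- list(girls = "girl", boys = "boy", total = c("girl", "boy"))
  wide <- coh[coh$condition == "with_analyzer", , drop = FALSE]
  wo <- coh[coh$condition == "without_analyzer", , drop = FALSE]
  wide <- wide[order(wide$child_id), ]
  wo <- wo[order(wo$child_id), ]

  cohort_summary <- do.call(rbind, lapply(names(groups), function(gn) {
    w <- wide[wide$sex %in% groups[[gn]], ]
    v <- wo[wo$sex %in% groups[[gn]], ]
    vars <- c(age_y = "age_y", height_cm = "height_cm",
              weight_kg = "weight_kg", fat_pct = "fat_pct", bmi = "bmi",
              bmi_z = "bmi_z", waist_cm = "waist_cm", tri_mm = "tri_mm",
              sub_mm = "sub_mm", hr_peak = "hr_peak", vo2peak = "vo2peak")
    base <- data.frame(group = gn, n = nrow(w),
                       variable = names(vars),
                       mean = vapply(vars, function(cl) mean(w[[cl]]),
                                     numeric(1)),
                       sd = vapply(vars, function(cl) stats::sd(w[[cl]]),
                                   numeric(1)),
                       stringsAsFactors = FALSE)
    perf <- data.frame(
      group = gn, n = nrow(w),
      variable = c("ms_with", "ms_without", "laps_with", "laps_without",
                   "time_with", "time_without"),
      mean = c(mean(w$max_speed_kmh), mean(v$max_speed_kmh),
               mean(w$laps), mean(v$laps),
               mean(w$time_s), mean(v$time_s)),
      sd = c(stats::sd(w$max_speed_kmh), stats::sd(v$max_speed_kmh),
             stats::sd(w$laps), stats::sd(v$laps),
             stats::sd(w$time_s), stats::sd(v$time_s)),
      stringsAsFactors = FALSE)
    rbind(base, perf)
  }))

  condition_comparison <- do.call(rbind, lapply(names(groups), function(gn) {
    w <- wide[wide$sex %in% groups[[gn]], ]
    v <- wo[wo$sex %in% groups[[gn]], ]
    do.call(rbind, lapply(
      c(max_speed_kmh = "max_speed_kmh", laps = "laps", time_s = "time_s"),
      function(cl) {
        pc <- paired_comparison(w[[cl]], v[[cl]],
                                d_denominator = config$d_denominator)
        data.frame(group = gn, variable = cl, n = pc$n,
                   mean_diff = pc$mean_diff,
                   ci_lower = pc$ci[1], ci_upper = pc$ci[2],
                   t = pc$t, p = pc$p, cohens_d = pc$cohens_d,
                   stringsAsFactors = FALSE)
      }))
  }))

  predictions <- predict_cohort(coh, profile = config$profile)

  merge_meta <- function(p) {
    meta <- wide[, c("child_id", "sex", "vo2peak", "fat_pct")]
    merge(p, meta[, c("child_id", "vo2peak", "fat_pct")], by = "child_id")
  }
  predictions <- merge_meta(predictions)

  prediction_summary <- do.call(rbind, lapply(1:22, function(id) {
    p <- predictions[predictions$equation_id == id, ]
    do.call(rbind, lapply(c("with_analyzer", "without_analyzer"),
                          function(cond) {
      pc <- p[p$condition == cond, ]
      do.call(rbind, lapply(names(groups), function(gn) {
        x <- pc$vo2peak_pred[pc$sex %in% groups[[gn]]]
        data.frame(equation_id = id, condition = cond, group = gn,
                   n = sum(!is.na(x)),
                   mean = if (all(is.na(x))) NA_real_ else
                     mean(x, na.rm = TRUE),
                   sd = if (all(is.na(x))) NA_real_ else
                     stats::sd(x, na.rm = TRUE),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  # difference tests against the without-analyzer predictions: the single
  # published per-equation "Diff" is reproducible under that convention
  difference_tests <- do.call(rbind, lapply(1:22, function(id) {
    do.call(rbind, lapply(c("with_analyzer", "without_analyzer"),
                          function(cond) {
      p <- predictions[predictions$equation_id == id &
                         predictions$condition == cond, ]
      p <- p[order(p$child_id), ]
      do.call(rbind, lapply(names(groups), function(gn) {
        pg <- p[p$sex %in% groups[[gn]], ]
        if (!nrow(pg) || any(is.na(pg$vo2peak_pred))) {
          return(data.frame(equation_id = id, condition = cond, group = gn,
                            n = 0L, mean_diff = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            t = NA_real_, p = NA_real_,
                            cohens_d = NA_real_, verdict = NA_character_,
                            stringsAsFactors = FALSE))
        }
        meas <- pg$vo2peak
        pred <- pg$vo2peak_pred
        if (config$fat_adjust && stats::var(pg$fat_pct) > 0) {
          d <- meas - pred
          fit <- stats::lm(d ~ fat_pct, data = pg)
          pred <- meas - (stats::residuals(fit) + stats::coef(fit)[1] +
                            stats::coef(fit)[2] * mean(pg$fat_pct))
        }
        pc <- paired_comparison(meas, pred,
                                d_denominator = config$d_denominator)
        data.frame(equation_id = id, condition = cond, group = gn,
                   n = pc$n, mean_diff = pc$mean_diff,
                   ci_lower = pc$ci[1], ci_upper = pc$ci[2],
                   t = pc$t, p = pc$p, cohens_d = pc$cohens_d,
                   verdict = classify_equation(pc$p, config$alpha),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  verdicts <- difference_tests[difference_tests$condition ==
                                 "without_analyzer",
                               c("equation_id", "group", "p", "verdict")]
  rownames(verdicts) <- NULL

  adequate_ids <- sort(unique(
    difference_tests$equation_id[!is.na(difference_tests$verdict) &
                                   difference_tests$verdict == "adequate"]))
  ba <- do.call(rbind, lapply(adequate_ids, function(id) {
    do.call(rbind, lapply(c("with_analyzer", "without_analyzer"),
                          function(cond) {
      p <- predictions[predictions$equation_id == id &
                         predictions$condition == cond, ]
      do.call(rbind, lapply(names(groups), function(gn) {
        pg <- p[p$sex %in% groups[[gn]], ]
        if (any(is.na(pg$vo2peak_pred)) ||
            stats::var(pg$vo2peak_pred) == 0) return(NULL)
        b <- bland_altman(pg$vo2peak, pg$vo2peak_pred, k = config$loa_k)
        v <- validity_stats(pg$vo2peak, pg$vo2peak_pred,
                            see_method = config$see_method)
        data.frame(equation_id = id, condition = cond, group = gn,
                   n = nrow(pg), bias = b$bias,
                   loa_lower = b$loa_lower, loa_upper = b$loa_upper,
                   ba_slope = b$ba_slope, ba_slope_p = b$ba_slope_p,
                   r = v$r, r_squared = v$r_squared, see = v$see,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  structure(list(
    screening = screening,
    cohort_summary = cohort_summary,
    condition_comparison = condition_comparison,
    predictions = predictions[, c("child_id", "sex", "condition",
                                  "equation_id", "vo2peak_pred")],
    prediction_summary = prediction_summary,
    difference_tests = difference_tests,
    bland_altman = ba,
    verdicts = verdicts,
    config = config
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  inc <- sum(x$screening$included)
  cat(sprintf("study_report: %d/%d children pass effort screening\n",
              inc, nrow(x$screening)))
  ade <- x$verdicts[x$verdicts$group == "total" &
                      !is.na(x$verdicts$verdict) &
                      x$verdicts$verdict == "adequate", "equation_id"]
  cat("adequate equations (total sample, without-analyzer trial): ",
      if (length(ade)) paste0("#", ade, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' Write a study report to CSV/JSON artifacts
#'
#' Emits one CSV per report table (fixed column order) plus the config as
#' JSON and the Bland-Altman point sets for adequate equations.
#'
#' @param report a [run_study()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, name) {
    if (!is.null(d)) {
      utils::write.csv(d, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  w(report$screening, "screening")
  w(report$cohort_summary, "cohort_summary")
  w(report$condition_comparison, "condition_comparison")
  w(report$predictions, "predictions")
  w(report$prediction_summary, "prediction_summary")
  w(report$difference_tests, "difference_tests")
  w(report$bland_altman, "bland_altman")
  w(report$verdicts, "verdicts")
  jsonlite::write_json(unclass(report$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
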