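# Published group summary statistics of the validation cohort (63 girls,
# 67 boys of 6-9 years). These printed means/SDs are inputs to the
# summary-statistics ("plug-in") mode: they let the per-equation predicted
# group means be reproduced without access to raw data.

#' Published summary statistics of the validation cohort
#'
#' @return data frame with one row per variable and columns
#'   `variable`, `girls_mean`, `girls_sd`, `boys_mean`, `boys_sd`,
#'   `total_mean`, `total_sd`. Group sizes are attached as the `"n"`
#'   attribute (`girls`, `boys`, `total`).
#' @export
reference_summary <- function() {
  m <- rbind(
    # variable            girls            boys             total
    age_y        = c(7.59, 0.91,    7.76, 0.97,    7.68, 0.94),
    height_cm    = c(128.70, 7.52,  130.14, 9.23,  129.44, 8.45),
    weight_kg    = c(29.22, 6.14,   31.02, 8.87,   30.15, 7.70),
    fat_pct      = c(16.92, 5.10,   15.59, 6.64,   16.23, 5.96),
    bmi          = c(17.50, 2.51,   17.97, 2.78,   17.74, 2.65),
    bmi_z        = c(0.53, 0.93,    0.73, 0.88,    0.63, 0.91),
    waist_cm     = c(56.72, 6.19,   58.95, 8.98,   57.87, 7.80),
    tri_mm       = c(11.70, 3.96,   10.11, 4.33,   10.88, 4.22),
    sub_mm       = c(6.76, 2.82,    6.39, 3.33,    6.57, 3.13),
    hr_peak      = c(193.42, 9.0,   194.09, 8.19,  193.77, 8.56),
    vo2peak      = c(46.97, 5.07,   49.69, 6.19,   48.37, 5.81),
    ms_with      = c(9.55, 0.42,    9.92, 0.77,    9.74, 0.65),
    ms_without   = c(9.44, 0.54,    9.88, 0.81,    9.67, 0.73),
    laps_with    = c(19.92, 7.03,   26.22, 12.66,  23.17, 10.76),
    laps_without = c(18.46, 8.19,   25.99, 12.99,  22.34, 11.52),
    time_with    = c(159.86, 52.21, 206.12, 87.45, 183.70, 75.90),
    time_without = c(149.96, 62.00, 207.76, 92.64, 179.75, 84.14)
  )
  d <- data.frame(variable = rownames(m),
                  girls_mean = m[, 1], girls_sd = m[, 2],
                  boys_mean = m[, 3], boys_sd = m[, 4],
                  total_mean = m[, 5], total_sd = m[, 6],
                  row.names = NULL, stringsAsFactors = FALSE)
  attr(d, "n") <- c(girls = 63L, boys = 67L, total = 130L)
  d
}

ref_value <- function(ref, variable, group, what = "mean") {
  ref[ref$variable == variable, paste0(group, "_", what)]
}

#' Plug-in group-mean predictions from published summary statistics
#'
#' Evaluates each of the 22 equations at a sex group's published mean
#' anthropometrics and trial results, the "summary-statistics mode" used
#' to reproduce printed per-equation predicted means. For strictly linear
#' equations the plug-in value equals the group mean of individual
#' predictions; equations with products of sampled inputs (for example a
#' speed-by-age interaction) differ by the within-group covariance, and
#' equations evaluated through nested logistics by much more.
#'
#' @param condition `"with"` (gas analyzer worn) or `"without"`.
#' @param profile see [evaluate_equation()]; defaults to `"table4"`, the
#'   reconciliation profile under which published group means reproduce.
#' @param ref a [reference_summary()]-shaped data frame (override to plug
#'   in a different study's summary table).
#' @return data frame with `equation_id`, `label`, `girls`, `boys` plug-in
#'   predictions (mL/kg/min, unrounded).
#' @export
plugin_predictions <- function(condition = c("with", "without"),
                               profile = c("table4", "as_printed"),
                               ref = reference_summary()) {
  condition <- match.arg(condition)
  profile <- match.arg(profile)
  listing <- list_equations()
  one_group <- function(group) {
    child <- list(
      sex = if (group == "girls") "girl" else "boy",
      age_y = ref_value(ref, "age_y", group),
      height_cm = ref_value(ref, "height_cm", group),
      weight_kg = ref_value(ref, "weight_kg", group),
      tri_mm = ref_value(ref, "tri_mm", group),
      bmi = ref_value(ref, "bmi", group),
      bmi_z = ref_value(ref, "bmi_z", group),
      waist_cm = ref_value(ref, "waist_cm", group),
      fat_pct = ref_value(ref, "fat_pct", group)
    )
    trial <- list(
      max_speed_kmh = ref_value(ref, paste0("ms_", condition), group),
      laps = ref_value(ref, paste0("laps_", condition), group),
      time_s = ref_value(ref, paste0("time_", condition), group)
    )
    vapply(listing$id, function(id)
      evaluate_equation(id, child, trial, profile = profile), numeric(1))
  }
  data.frame(equation_id = listing$id, label = listing$label,
             girls = one_group("girls"), boys = one_group("boys"),
             stringsAsFactors = FALSE)
}
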