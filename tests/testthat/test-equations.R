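test_that("registry lists exactly 22 equations in order with correct slots", {
  reg <- list_equations()
  expect_identical(reg$id, 1:22)
  expect_match(reg$required_inputs[reg$id == 2], "tri_mm")
  expect_setequal(strsplit(reg$required_inputs[reg$id == 21], ",")[[1]],
                  c("laps", "bmi_z", "height_m", "age_mo"))
  expect_match(reg$required_inputs[reg$id == 19], "waist_cm")
  # sex-free equations carry no coding
  expect_true(all(is.na(reg$girl_code[reg$id %in% c(1, 15, 16, 17)])))
  expect_identical(sum(reg$has_table4_override), 2L)
  js <- equations_to_json()
  expect_identical(nrow(jsonlite::fromJSON(js)), 22L)
})

test_that("spot predictions reproduce published group means", {
  girl <- list(sex = "girl", age_y = 7.59, weight_kg = 29.22,
               tri_mm = 11.70, bmi = 17.50, waist_cm = 56.72)
  trial <- list(max_speed_kmh = 9.55, laps = 19.92)
  expect_equal(evaluate_equation(4, girl, trial), 45.60, tolerance = 0.001)
  expect_equal(evaluate_equation(2, girl, trial), 42.84, tolerance = 0.001)
  expect_lt(abs(evaluate_equation(19, girl, trial) - 35.81), 0.02)
  expect_lt(abs(evaluate_equation(18, girl, trial) - 41.86), 0.02)
  expect_lt(abs(evaluate_equation(8, girl, trial) - 43.04), 0.02)
})

test_that("evaluate_all reports 22 entries and flags missing inputs", {
  preds <- evaluate_all_equations(full_child(), full_trial())
  expect_length(preds, 22L)
  expect_true(all(is.finite(preds)))

  child <- full_child()
  child$waist_cm <- NULL
  preds <- evaluate_all_equations(child, full_trial())
  expect_true(is.na(preds[["eq19"]]))
  expect_false(is.na(preds[["eq20"]]))   # uses fat %, not waist
  expect_identical(sum(is.na(preds)), 1L)
  expect_named(attr(preds, "missing_inputs"), "eq19")
  expect_error(evaluate_equation(19, child, full_trial()), "waist_cm")
  expect_error(evaluate_equation(23, full_child(), full_trial()), "unknown")
})

test_that("predictions are non-decreasing in speed for the speed equations", {
  speeds <- seq(8, 14, by = 0.5)
  for (id in c(1, 2, 3, 4, 6, 8, 9, 11, 14)) {
    for (sex in c("girl", "boy")) {
      child <- full_child(sex)
      vals <- vapply(speeds, function(s)
        evaluate_equation(id, child, list(max_speed_kmh = s)), numeric(1))
      expect_true(all(diff(vals) >= 0), label = sprintf("eq %d (%s)", id, sex))
    }
  }
})

test_that("nested-logistic equations are finite and bounded on the box", {
  set.seed(42)
  n <- 1e5
  box <- srtvalid:::SRT_INPUT_BOX
  rbox <- function(nm) stats::runif(n, box[[nm]][1], box[[nm]][2])
  v <- list(age_y = rbox("age_y"), mass_kg = rbox("mass_kg"),
            height_cm = rbox("height_cm"), time_min = rbox("time_min"),
            laps = rbox("laps"), bmi = rbox("bmi"))
  g10 <- sample(1:2, n, replace = TRUE)
  out10 <- srtvalid:::eq10_eval(v, g10)
  expect_true(all(is.finite(out10)))
  # affine range anchored by the output unscaling constants
  lo <- (0 + 0.478945173945) / 0.0204587840012
  hi <- (1 + 0.478945173945) / 0.0204587840012
  expect_true(all(out10 > lo & out10 < hi))

  g13 <- sample(0:1, n, replace = TRUE)
  out13 <- srtvalid:::eq13_eval(v, g13)
  expect_true(all(is.finite(out13)))
  expect_true(all(out13 > 29.17 & out13 < 29.17 + 39.83))
})

test_that("nested-logistic constants match the frozen transcription", {
  k10 <- srtvalid:::EQ10_CONST
  expect_equal(k10$h1, c(-1.03329, 0.54719, 0.61542, -0.51381, -0.92239,
                         -0.34242))
  expect_equal(k10$out, c(-0.95905, 2.19501, -2.567, -0.05105))
  expect_equal(k10$unscale, c(-0.478945173945, 0.0204587840012))
  expect_equal(k10$scale$E1, c(0.0842105263158, -0.0684210526316))
  k13 <- srtvalid:::EQ13_CONST
  expect_equal(k13$h4, c(8.144, -0.724, -0.329, 6.170, -0.573, 0.373,
                         -4.679))
  expect_equal(k13$unscale, c(39.83, 29.17))
})

test_that("the table4 profile applies exactly the two documented overrides", {
  child_g <- full_child("girl"); child_b <- full_child("boy")
  trial <- full_trial()
  # #6: printed coding M=1/F=0; compat swaps it, so the two profiles differ
  # by the full 2.21 coefficient for each sex
  d6g <- evaluate_equation(6, child_g, trial) -
    evaluate_equation(6, child_g, trial, profile = "table4")
  d6b <- evaluate_equation(6, child_b, trial) -
    evaluate_equation(6, child_b, trial, profile = "table4")
  expect_equal(d6g, 2.21)
  expect_equal(d6b, -2.21)
  # #11: compat zeroes the gender x age interaction (only boys change)
  expect_equal(evaluate_equation(11, child_b, trial) -
                 evaluate_equation(11, child_b, trial, profile = "table4"),
               0.34787 * 1 * child_b$age_y)
  expect_equal(evaluate_equation(11, child_g, trial),
               evaluate_equation(11, child_g, trial, profile = "table4"))
  # all other equations are identical across profiles
  a <- evaluate_all_equations(full_child(), trial)
  b <- evaluate_all_equations(full_child(), trial, profile = "table4")
  same <- setdiff(1:22, c(6, 11))
  expect_equal(a[same], b[same])
})

test_that("off-box inputs warn rather than error", {
  expect_warning(
    evaluate_equation(4, list(sex = "girl", age_y = 8),
                      list(max_speed_kmh = 25)),
    "physiological box")
})

test_that("vectorised cohort prediction agrees with scalar evaluation", {
  coh <- generate_cohort(seed = 7, n_girls = 5, n_boys = 5)
  preds <- predict_cohort(coh, profile = "table4")
  for (i in c(1, 8, 15)) {
    row <- coh[i, ]
    for (id in c(1, 5, 10, 13, 21)) {
      scalar <- evaluate_equation(
        id, row, list(max_speed_kmh = row$max_speed_kmh, laps = row$laps,
                      time_s = row$time_s), profile = "table4")
      vec <- preds$vo2peak_pred[preds$equation_id == id &
                                  preds$child_id == row$child_id &
                                  preds$condition == row$condition]
      expect_equal(vec, scalar, label = sprintf("eq %d row %d", id, i))
    }
  }
})

test_that("reporting rounds half away from zero", {
  expect_equal(round_half_up(34.495), 34.50)
  expect_equal(round_half_up(-34.495), -34.50)
  expect_equal(round_half_up(1.005), 1.01)
})
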