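# Registry of 22 published VO2peak predictive equations for children and
# youth performing the 20-m shuttle run test, each transcribed with its own
# sex coding and units. All evaluators are pure functions of a resolved
# input vector and return mL/kg/min without internal rounding.
#
# Input slot names used by the registry:
#   speed     maximal shuttle speed, km/h
#   laps      total laps completed
#   time_min  total running time, minutes
#   age_y     age, years
#   age_mo    age, whole months (round(12 * years))
#   height_cm / height_m
#   mass_kg   body mass
#   bmi       kg/m^2
#   bmi_z     BMI z-score
#   waist_cm  waist circumference
#   tri_mm    triceps skinfold (registry slot name; two sources print the
#             unit as cm but their coefficients only make sense on the
#             measured-value scale, so values are passed through as given)
#   fat_pct   percent body fat
#
# Two codings as printed contradict the source study's own group-mean
# reproduction: equation #6 only reproduces with the female/male coding
# swapped, and #11 only with its gender x age interaction zeroed. The
# default profile evaluates formulas exactly as printed; the
# "table4" profile applies those two documented overrides.

# ---- nested-logistic constants (frozen transcription tables) -------------

EQ10_CONST <- list(
  # input scalings: slot * a + b
  scale = list(
    A1 = c(0.8, -0.7),                       # sex code: boy 1 / girl 2
    B1 = c(0.114285714286, -1.38571428571),  # age, years
    C1 = c(0.012213740458, -0.406870229008), # weight, kg
    D1 = c(0.0195598978221, -2.76356892177), # height, cm
    E1 = c(0.0842105263158, -0.0684210526316) # total time, min
  ),
  # hidden nodes: weights on (A1, B1, C1, D1, E1) then bias
  h1 = c(-1.03329, 0.54719, 0.61542, -0.51381, -0.92239, -0.34242),
  h2 = c(-1.19367, -1.54924, -3.18931, 0.77773, 3.31887, -0.55696),
  h3 = c(1.38191, -2.14449, 0.0485, 0.10879, -4.90052, 0.53905),
  out = c(-0.95905, 2.19501, -2.567, -0.05105),
  unscale = c(-0.478945173945, 0.0204587840012)
)

EQ13_CONST <- list(
  # columns: stage/11, gender, (age-10)/8, (height-141)/46, (weight-37)/59,
  # (bmi-16.23)/13.68, bias. Node 2's third weight multiplies
  # (gender-10)/8 as printed in the source (a likely misprint for age,
  # kept symbol-for-symbol).
  h1 = c(-5.309, -1.968, 4.394, 1.881, 3.078, 4.429, -4.302),
  h2 = c(1.790, 2.253, 1.770, -1.060, 4.978, -3.610, -2.705),
  h3 = c(5.528, -6.357, -1.068, 0.663, 1.333, 0.825, -1.608),
  h4 = c(8.144, -0.724, -0.329, 6.170, -0.573, 0.373, -4.679),
  out = c(-1.782, 9.988, 6.384, -4.278, -3.886),
  unscale = c(39.83, 29.17)
)

eq10_eval <- function(v, g) {
  k <- EQ10_CONST
  raw <- list(A1 = g, B1 = v[["age_y"]], C1 = v[["mass_kg"]],
              D1 = v[["height_cm"]], E1 = v[["time_min"]])
  s <- mapply(function(x, sc) x * sc[1] + sc[2], raw, k$scale[names(raw)],
              SIMPLIFY = FALSE)
  S <- do.call(cbind, s)                       # n x 5, works for n = 1 too
  node <- function(w) sigmoid(drop(S %*% w[1:5]) + w[6])
  h <- sigmoid(node(k$h1) * k$out[1] + node(k$h2) * k$out[2] +
               node(k$h3) * k$out[3] + k$out[4])
  (h - k$unscale[1]) / k$unscale[2]
}

eq13_eval <- function(v, g) {
  k <- EQ13_CONST
  n <- max(length(v[["laps"]]), length(g))
  X <- cbind(v[["laps"]] / 11,
             rep(g, length.out = n),
             (v[["age_y"]] - 10) / 8,
             (v[["height_cm"]] - 141) / 46,
             (v[["mass_kg"]] - 37) / 59,
             (v[["bmi"]] - 16.23) / 13.68)
  # node 2 uses (gender - 10)/8 in its third slot, as printed
  X2 <- X
  X2[, 3] <- (rep(g, length.out = n) - 10) / 8
  node <- function(w, M) sigmoid(drop(M %*% w[1:6]) + w[7])
  h <- sigmoid(node(k$h1, X) * k$out[1] + node(k$h2, X2) * k$out[2] +
               node(k$h3, X) * k$out[3] + node(k$h4, X) * k$out[4] +
               k$out[5])
  h * k$unscale[1] + k$unscale[2]
}

# ---- registry ------------------------------------------------------------

# each entry: label (first author, year), needs (input slots), coding
# (girl/boy numeric code, NULL when sex-free), fn(v, g), and optional
# compat overrides applied under the "table4" profile.
srt_registry <- function() {
  list(
    list(id = 1L, label = "Leger et al. (1988)",
         needs = c("speed", "age_y"), coding = NULL,
         fn = function(v, g)
           31.025 + 3.238 * v[["speed"]] - 3.248 * v[["age_y"]] +
           0.1536 * v[["age_y"]] * v[["speed"]]),
    list(id = 2L, label = "Barnett et al. (1993)",
         needs = c("tri_mm", "speed"), coding = c(girl = 1, boy = 0),
         fn = function(v, g)
           28.3 - 2.1 * g - 0.7 * v[["tri_mm"]] + 2.6 * v[["speed"]]),
    list(id = 3L, label = "Barnett et al. (1993)",
         needs = c("mass_kg", "speed"), coding = c(girl = 1, boy = 0),
         fn = function(v, g)
           25.8 - 6.6 * g - 0.2 * v[["mass_kg"]] + 3.2 * v[["speed"]]),
    list(id = 4L, label = "Barnett et al. (1993)",
         needs = c("age_y", "speed"), coding = c(girl = 1, boy = 0),
         fn = function(v, g)
           24.2 - 5.0 * g - 0.8 * v[["age_y"]] + 3.4 * v[["speed"]]),
    list(id = 5L, label = "Fernhall et al. (1998)",
         needs = c("laps", "bmi"), coding = c(girl = 2, boy = 1),
         fn = function(v, g)
           0.35 * v[["laps"]] - 0.59 * v[["bmi"]] - 4.61 * g + 50.6),
    list(id = 6L, label = "Matsuzaka et al. (2004)",
         needs = c("age_y", "bmi", "speed"), coding = c(girl = 0, boy = 1),
         compat = list(coding = c(girl = 1, boy = 0)),
         fn = function(v, g)
           25.9 - 2.21 * g - 0.0449 * v[["age_y"]] - 0.831 * v[["bmi"]] +
           4.12 * v[["speed"]]),
    list(id = 7L, label = "Matsuzaka et al. (2004)",
         needs = c("age_y", "bmi", "laps"), coding = c(girl = 1, boy = 0),
         fn = function(v, g)
           61.1 - 2.20 * g - 0.462 * v[["age_y"]] - 0.862 * v[["bmi"]] +
           0.192 * v[["laps"]]),
    list(id = 8L, label = "Mahar et al. (2006)",
         needs = c("speed", "mass_kg"), coding = c(girl = 0, boy = 1),
         fn = function(v, g)
           47.438 + v[["speed"]] * 0.142 + g * 5.134 -
           v[["mass_kg"]] * 0.197),
    list(id = 9L, label = "Mahar et al. (2006)",
         needs = c("speed", "mass_kg"), coding = c(girl = 0, boy = 1),
         fn = function(v, g)
           50.945 + v[["speed"]] * 0.126 + g * 4.946 -
           v[["mass_kg"]] * 0.655),
    list(id = 10L, label = "Ruiz et al. (2008)",
         needs = c("age_y", "mass_kg", "height_cm", "time_min"),
         coding = c(girl = 2, boy = 1),
         fn = eq10_eval),
    list(id = 11L, label = "Mahar et al. (2011)",
         needs = c("speed", "bmi", "age_y"), coding = c(girl = 0, boy = 1),
         compat = list(fn = function(v, g)
           41.76799 + 0.49261 * v[["speed"]] - 0.00290 * v[["speed"]]^2 -
           0.61613 * v[["bmi"]]),
         fn = function(v, g)
           41.76799 + 0.49261 * v[["speed"]] - 0.00290 * v[["speed"]]^2 -
           0.61613 * v[["bmi"]] + 0.34787 * g * v[["age_y"]]),
    list(id = 12L, label = "Silva et al. (2012)",
         needs = c("bmi", "time_min"), coding = c(girl = 0, boy = 1),
         fn = function(v, g)
           43.313 + 4.567 * g - 0.560 * v[["bmi"]] +
           2.785 * v[["time_min"]]),
    list(id = 13L, label = "Silva et al. (2012)",
         needs = c("laps", "age_y", "height_cm", "mass_kg", "bmi"),
         coding = c(girl = 0, boy = 1),
         fn = eq13_eval),
    list(id = 14L, label = "Quinart et al. (2014)",
         needs = c("speed", "age_y", "bmi"), coding = c(girl = 0, boy = 1),
         fn = function(v, g)
           19.66 + 2.21 * v[["speed"]] + 0.05 * v[["age_y"]] + 2.08 * g -
           0.38 * v[["bmi"]]),
    list(id = 15L, label = "Burns et al. (2015)",
         needs = c("laps", "age_y"), coding = NULL,
         fn = function(v, g)
           45.619 + 0.353 * v[["laps"]] - 1.121 * v[["age_y"]]),
    list(id = 16L, label = "Mahar et al. (2018)",
         needs = c("laps", "age_y"), coding = NULL,
         fn = function(v, g)
           44.862 + 0.347 * v[["laps"]] - 1.050 * v[["age_y"]]),
    list(id = 17L, label = "Mahar et al. (2018)",
         needs = c("laps", "age_y", "bmi"), coding = NULL,
         fn = function(v, g)
           49.367 + v[["laps"]] * 0.331 - v[["age_y"]] * 0.777 -
           v[["bmi"]] * 0.369),
    list(id = 18L, label = "Scott et al. (2019)",
         needs = c("laps", "bmi", "age_y"), coding = c(girl = 0, boy = 1),
         fn = function(v, g)
           52.934 + 0.256 * v[["laps"]] - 0.924 * v[["bmi"]] +
           0.468 * g * v[["age_y"]]),
    list(id = 19L, label = "Ayala-Guzman & Ortiz-Hernandez (2021)",
         needs = c("age_y", "laps", "waist_cm"), coding = c(girl = 1, boy = 0),
         fn = function(v, g)
           44.942 + 0.646 * v[["age_y"]] - 6.586 * g + 0.318 * v[["laps"]] -
           0.243 * v[["waist_cm"]]),
    list(id = 20L, label = "Ayala-Guzman & Ortiz-Hernandez (2021)",
         needs = c("age_y", "laps", "fat_pct"), coding = c(girl = 1, boy = 0),
         fn = function(v, g)
           37.009 + 0.408 * v[["age_y"]] - 4.759 * g + 0.284 * v[["laps"]] -
           0.312 * v[["fat_pct"]]),
    list(id = 21L, label = "Menezes-Junior et al. (2022)",
         needs = c("laps", "bmi_z", "height_m", "age_mo"),
         coding = c(girl = 0, boy = 1),
         fn = function(v, g)
           46.802 + 0.381 * v[["laps"]] - 3.682 * v[["bmi_z"]] -
           0.0568 * v[["height_m"]] * v[["age_mo"]] + 3.078 * g),
    list(id = 22L, label = "Menezes-Junior et al. (2022)",
         needs = c("laps", "bmi_z", "fat_pct", "height_m", "age_mo"),
         coding = c(girl = 0, boy = 1),
         fn = function(v, g)
           54.051 + 0.324 * v[["laps"]] - 2.626 * v[["bmi_z"]] -
           0.276 * v[["fat_pct"]] - 0.0493 * v[["height_m"]] * v[["age_mo"]] +
           2.016 * g)
  )
}

# physiological input box on which every evaluator must stay finite
SRT_INPUT_BOX <- list(
  speed = c(8, 16), laps = c(0, 150), time_min = c(0, 25),
  age_y = c(5, 19), height_cm = c(100, 190), mass_kg = c(15, 90),
  bmi = c(12, 35), bmi_z = c(-3, 3), waist_cm = c(40, 110),
  tri_mm = c(3, 40), fat_pct = c(5, 45)
)

# ---- input resolution ----------------------------------------------------

# Build the resolved input vector for one child and one trial. `child` is a
# named list / one-row data frame with sex, age_y, height_cm, weight_kg,
# tri_mm, bmi, bmi_z, waist_cm, fat_pct (missing fields allowed); `trial`
# carries max_speed_kmh, laps, time_s.
resolve_inputs <- function(child, trial) {
  child <- as.list(child)
  trial <- as.list(trial)
  num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  age <- num(child$age_y)
  hgt <- num(child$height_cm)
  v <- c(
    speed = num(trial$max_speed_kmh),
    laps = num(trial$laps),
    time_min = num(trial$time_s) / 60,
    age_y = age,
    age_mo = if (is.na(age)) NA_real_ else as.numeric(age_months(age)),
    height_cm = hgt,
    height_m = hgt / 100,
    mass_kg = num(child$weight_kg),
    bmi = num(child$bmi),
    bmi_z = num(child$bmi_z),
    waist_cm = num(child$waist_cm),
    tri_mm = num(child$tri_mm),
    fat_pct = num(child$fat_pct)
  )
  v
}

registry_entry <- function(id) {
  reg <- srt_registry()
  if (length(id) != 1L || !id %in% seq_len(22L)) {
    stop("unknown equation id (expected 1..22)", call. = FALSE)
  }
  reg[[as.integer(id)]]
}

#' Evaluate one VO2peak prediction equation
#'
#' Evaluates equation `id` (1-22) for one child and one shuttle-run trial,
#' using that equation's own sex coding and units. Values are returned at
#' full precision; round with [round_half_up()] for table-style reporting.
#'
#' @param id equation number, 1 to 22.
#' @param child named list or one-row data frame with `sex` plus the
#'   anthropometric fields the equation needs (`age_y`, `height_cm`,
#'   `weight_kg`, `bmi`, `bmi_z`, `waist_cm`, `tri_mm`, `fat_pct`).
#' @param trial named list with `max_speed_kmh`, `laps`, `time_s` (only the
#'   slots the equation needs must be present).
#' @param profile `"as_printed"` (default) evaluates every formula exactly
#'   as published; `"table4"` additionally applies two documented
#'   reconciliations (swapped sex coding in #6, zeroed gender-age
#'   interaction in #11) needed to reproduce the source study's group
#'   means.
#' @return predicted VO2peak in mL/kg/min.
#' @export
#' @examples
#' girl <- list(sex = "girl", age_y = 7.59)
#' evaluate_equation(4, girl, list(max_speed_kmh = 9.55))  # 45.598
evaluate_equation <- function(id, child, trial,
                              profile = c("as_printed", "table4")) {
  profile <- match.arg(profile)
  e <- registry_entry(id)
  v <- resolve_inputs(child, trial)
  missing <- e$needs[is.na(v[e$needs])]
  if (length(missing)) {
    stop(sprintf("equation #%d is missing input(s): %s", e$id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  off <- vapply(e$needs, function(nm) {
    box <- SRT_INPUT_BOX[[nm]]
    if (is.null(box)) return(FALSE)
    v[[nm]] < box[1] || v[[nm]] > box[2]
  }, logical(1))
  if (any(off)) {
    warning(sprintf("equation #%d: input(s) outside the physiological box: %s",
                    e$id, paste(e$needs[off], collapse = ", ")),
            call. = FALSE)
  }
  coding <- e$coding
  fn <- e$fn
  if (profile == "table4" && !is.null(e$compat)) {
    if (!is.null(e$compat$coding)) coding <- e$compat$coding
    if (!is.null(e$compat$fn)) fn <- e$compat$fn
  }
  g <- 0
  if (!is.null(coding)) {
    sx <- match_sex(as.list(child)$sex)
    g <- unname(coding[[sx]])
  }
  fn(v, g)
}

#' Evaluate all 22 equations for one child and trial
#'
#' Equations whose inputs are unavailable are reported as `NA`, never as
#' zero; the names of the missing inputs are attached as the
#' `"missing_inputs"` attribute.
#'
#' @inheritParams evaluate_equation
#' @return named numeric vector `eq1`..`eq22` of predictions in mL/kg/min.
#' @export
evaluate_all_equations <- function(child, trial,
                                   profile = c("as_printed", "table4")) {
  profile <- match.arg(profile)
  v <- resolve_inputs(child, trial)
  reg <- srt_registry()
  out <- rep(NA_real_, 22L)
  names(out) <- paste0("eq", 1:22)
  miss <- list()
  for (e in reg) {
    lack <- e$needs[is.na(v[e$needs])]
    if (length(lack)) {
      miss[[paste0("eq", e$id)]] <- lack
    } else {
      out[e$id] <- evaluate_equation(e$id, child, trial, profile = profile)
    }
  }
  attr(out, "missing_inputs") <- miss
  out
}

#' Predict VO2peak for every row of a long-format cohort
#'
#' Vectorised evaluation of all 22 equations over a cohort data frame
#' (one row per child x condition, as produced by [generate_cohort()]).
#'
#' @param cohort cohort data frame with the documented columns.
#' @param profile see [evaluate_equation()].
#' @return long data frame: `child_id`, `sex`, `condition`, `equation_id`,
#'   `vo2peak_pred` (NA where an equation's inputs are absent).
#' @export
predict_cohort <- function(cohort, profile = c("as_printed", "table4")) {
  profile <- match.arg(profile)
  col <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else
    rep(NA_real_, nrow(cohort))
  age <- col("age_y")
  v <- list(
    speed = col("max_speed_kmh"), laps = col("laps"),
    time_min = col("time_s") / 60,
    age_y = age, age_mo = round(12 * age),
    height_cm = col("height_cm"), height_m = col("height_cm") / 100,
    mass_kg = col("weight_kg"), bmi = col("bmi"), bmi_z = col("bmi_z"),
    waist_cm = col("waist_cm"), tri_mm = col("tri_mm"),
    fat_pct = col("fat_pct")
  )
  sx <- match_sex(cohort$sex)
  out <- lapply(srt_registry(), function(e) {
    coding <- e$coding
    fn <- e$fn
    if (profile == "table4" && !is.null(e$compat)) {
      if (!is.null(e$compat$coding)) coding <- e$compat$coding
      if (!is.null(e$compat$fn)) fn <- e$compat$fn
    }
    g <- if (is.null(coding)) rep(0, nrow(cohort)) else
      unname(coding[sx])
    ok <- !Reduce(`|`, lapply(e$needs, function(nm) is.na(v[[nm]])))
    pred <- rep(NA_real_, nrow(cohort))
    if (any(ok)) {
      vs <- lapply(v, function(x) x[ok])
      pred[ok] <- fn(vs, g[ok])
    }
    data.frame(child_id = cohort$child_id, sex = sx,
               condition = cohort$condition, equation_id = e$id,
               vo2peak_pred = pred, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Registry listing of the 22 prediction equations
#'
#' @return data frame with one row per equation: `id`, `label`,
#'   `required_inputs` (comma-separated slot names), `girl_code`,
#'   `boy_code` (NA for sex-free equations), and `has_table4_override`.
#' @export
list_equations <- function() {
  reg <- srt_registry()
  data.frame(
    id = vapply(reg, `[[`, integer(1), "id"),
    label = vapply(reg, `[[`, character(1), "label"),
    required_inputs = vapply(reg, function(e)
      paste(e$needs, collapse = ","), character(1)),
    girl_code = vapply(reg, function(e)
      if (is.null(e$coding)) NA_real_ else e$coding[["girl"]], numeric(1)),
    boy_code = vapply(reg, function(e)
      if (is.null(e$coding)) NA_real_ else e$coding[["boy"]], numeric(1)),
    has_table4_override = vapply(reg, function(e)
      !is.null(e$compat), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Export the equation registry as JSON
#'
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
equations_to_json <- function(path = NULL) {
  js <- jsonlite::toJSON(list_equations(), dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
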