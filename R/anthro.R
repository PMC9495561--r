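# Anthropometric derivations used by the prediction equations: Slaughter
# two-skinfold percent body fat (with its 35-mm branch point), body mass
# index, and the Tanaka age-predicted maximal heart rate.

#' Slaughter percent body fat from triceps + subscapular skinfolds
#'
#' Two-compartment percent body fat for children from the sum
#' S = triceps + subscapular (mm). For S below 35 mm a sex-specific
#' quadratic applies; above 35 mm a sex-specific linear form applies:
#'
#' * boys,  S < 35: `1.21 S - 0.008 S^2 - 1.7`
#' * girls, S < 35: `1.33 S - 0.013 S^2 - 2.5`
#' * boys,  S > 35: `0.546 S + 9.7`
#' * girls, S > 35: `0.783 S + 1.6`
#'
#' The two branches do not meet at S = 35; exactly 35 mm is assigned to the
#' quadratic (low-sum) branch by default, following the original "<= 35"
#' threshold. Set `boundary = "high"` to assign it to the linear branch.
#'
#' @param triceps,subscapular skinfold thicknesses in mm, both > 0
#'   (vectorised).
#' @param sex character vector, `"girl"` or `"boy"`.
#' @param boundary branch for S exactly 35 mm: `"low"` (default) or `"high"`.
#' @return percent body fat.
#' @export
#' @examples
#' slaughter_fat_pct(10, 10, "boy")   # 19.30
#' slaughter_fat_pct(20, 20, "boy")   # 31.54 (linear branch)
slaughter_fat_pct <- function(triceps, subscapular, sex,
                              boundary = c("low", "high")) {
  boundary <- match.arg(boundary)
  if (any(!is.finite(triceps)) || any(triceps <= 0) ||
      any(!is.finite(subscapular)) || any(subscapular <= 0)) {
    stop("skinfolds must be positive", call. = FALSE)
  }
  sex <- match_sex(sex)
  s <- triceps + subscapular
  low <- if (boundary == "low") s <= 35 else s < 35
  boy <- rep_len(sex == "boy", length(s))
  low_val <- ifelse(boy, 1.21 * s - 0.008 * s^2 - 1.7,
                         1.33 * s - 0.013 * s^2 - 2.5)
  high_val <- ifelse(boy, 0.546 * s + 9.7,
                          0.783 * s + 1.6)
  ifelse(low, low_val, high_val)
}

#' Body mass index
#'
#' @param body_mass kg, > 0.
#' @param height cm, > 0.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(body_mass, height) {
  if (any(!is.finite(body_mass)) || any(body_mass <= 0) ||
      any(!is.finite(height)) || any(height <= 0)) {
    stop("body mass and height must be positive", call. = FALSE)
  }
  body_mass / (height / 100)^2
}

#' Tanaka age-predicted maximal heart rate
#'
#' `208 - 0.7 * age`, the age-predicted HRmax used as the heart-rate anchor
#' of the maximal-effort criteria.
#'
#' @param age years, > 0.
#' @return predicted HRmax in beats per minute.
#' @export
tanaka_hrmax <- function(age) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("'age' must be positive", call. = FALSE)
  }
  208 - 0.7 * age
}

#' Age in months for equations that consume months
#'
#' `round(12 * years)`: equations fitted on age in months are evaluated at
#' the nearest whole month.
#'
#' @param age_years age in years.
#' @return integer months.
#' @export
age_months <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years <= 0)) {
    stop("'age_years' must be positive", call. = FALSE)
  }
  as.integer(round(12 * age_years))
}

# normalise sex labels; accepts "girl"/"boy" (and "f"/"m" shorthands)
match_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female")] <- "girl"
  s[s %in% c("m", "male")] <- "boy"
  if (any(!s %in% c("girl", "boy"))) {
    stop("'sex' must be \"girl\" or \"boy\"", call. = FALSE)
  }
  s
}
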