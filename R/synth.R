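# Synthetic cohort generator.
#
# Emulates the statistical structure the validation analysis assumes: two
# sex groups of children with published marginal moments for age, size,
# skinfolds, waist and BMI z-score; two shuttle-run trials per child (with
# and without the portable gas analyzer, "PGA") whose maximal speeds sit on
# the protocol grid and differ by a configurable paired shift; and a
# measured VO2peak generated from a linear link on with-analyzer speed and
# age. Marginal moments are the stated targets; all cross-correlations are
# design choices (no covariances are published) and only the marginals are
# asserted by the tests.

#' Default cohort parameters
#'
#' Returns the parameter set calibrated to the published group summary
#' statistics of the validation cohort (63 girls, 67 boys): per-sex
#' means/SDs for age, height, body mass, skinfolds, waist, BMI z-score,
#' maximal with-analyzer speed and peak heart rate; the paired
#' with-minus-without speed shift (SDs back-calculated from the printed
#' 95% CIs); and the VO2peak linear link. Gas-exchange screening knobs
#' (RER moments, ventilatory-threshold and subjective-sign probabilities)
#' are calibration choices set so that roughly the published share of
#' trials (about 4-5%) fails maximal-effort screening.
#'
#' @return object of class `cohort_params`: a list with `girls`, `boys`
#'   (each holding `n` and `mean`/`sd` pairs), shared `vo2_link`
#'   (intercept, speed and age slopes, residual SD), `rer`, `vt2_prob`,
#'   `subjective_prob`, `vo2_bounds` and `correlations`.
#' @export
cohort_params <- function() {
  sex_block <- function(n, age, height, mass, tri, sub, waist, bmi_z,
                        ms, cond_shift, hr) {
    list(n = n, age = age, height = height, mass = mass, tri = tri,
         sub = sub, waist = waist, bmi_z = bmi_z, ms = ms,
         cond_shift = cond_shift, hr = hr)
  }
  structure(list(
    girls = sex_block(63L,
      age = c(7.59, 0.91), height = c(128.70, 7.52), mass = c(29.22, 6.14),
      tri = c(11.70, 3.96), sub = c(6.76, 2.82), waist = c(56.72, 6.19),
      bmi_z = c(0.53, 0.93), ms = c(9.55, 0.42),
      cond_shift = c(0.11, 0.34), hr = c(193.42, 9.0)),
    boys = sex_block(67L,
      age = c(7.76, 0.97), height = c(130.14, 9.23), mass = c(31.02, 8.87),
      tri = c(10.11, 4.33), sub = c(6.39, 3.33), waist = c(58.95, 8.98),
      bmi_z = c(0.73, 0.88), ms = c(9.92, 0.77),
      cond_shift = c(0.04, 0.29), hr = c(194.09, 8.19)),
    vo2_link = c(intercept = -26.24, speed_slope = 9.0, age_slope = -1.7,
                 residual_sd = 2.5),
    rer = c(1.09, 0.06),
    vt2_prob = 0.98,
    subjective_prob = 0.99,
    vo2_bounds = c(20, 80),
    correlations = c(age_height = 0.7, height_mass = 0.7, age_mass = 0.5,
                     mass_skinfold = 0.6)
  ), class = "cohort_params")
}

validate_params <- function(params) {
  for (sx in c("girls", "boys")) {
    b <- params[[sx]]
    if (b$n < 2) stop("need at least 2 children per sex", call. = FALSE)
    for (f in c("age", "height", "mass", "tri", "sub", "waist", "bmi_z",
                "ms", "cond_shift", "hr")) {
      if (b[[f]][2] < 0) {
        stop(sprintf("negative SD for %s (%s)", f, sx), call. = FALSE)
      }
    }
  }
  if (params$vo2_link[["residual_sd"]] < 0 || params$rer[2] < 0) {
    stop("negative SD", call. = FALSE)
  }
  invisible(params)
}

# lap-by-lap protocol table used to place terminations inside stages;
# built once per cohort from the same walk as laps_to_outcome()
protocol_lap_table <- function(n_laps = 400L) {
  stage <- integer(n_laps)
  cum_time <- numeric(n_laps)
  t <- 0
  for (lap in seq_len(n_laps)) {
    s <- as.integer(t %/% SRT_STAGE_SECONDS) + 1L
    stage[lap] <- s
    t <- t + (SRT_LAP_METRES * 3.6) / stage_speed(s)
    cum_time[lap] <- t
  }
  data.frame(lap = seq_len(n_laps), stage = stage, cum_time = cum_time)
}

# map a standard-normal draw to a lognormal with the target mean/SD:
# positive-support fields (mass, skinfolds, waist) keep their published
# moments exactly while staying physical, which a truncated normal cannot
# do for skinfolds whose CV reaches ~0.4
lnorm_from_z <- function(z, mean, sd) {
  if (sd == 0) return(rep(mean, length(z)))
  s2 <- log(1 + (sd / mean)^2)
  exp(log(mean) - s2 / 2 + sqrt(s2) * z)
}

# snap a latent continuous speed to the 8.0 + 0.5k protocol grid
snap_speed <- function(s) {
  pmax(SRT_START_SPEED,
       SRT_START_SPEED +
         SRT_SPEED_INCREMENT * round((s - SRT_START_SPEED) /
                                       SRT_SPEED_INCREMENT))
}

#' Generate a synthetic cohort
#'
#' Each child gets two shuttle-run trials (condition `"with_analyzer"`
#' then `"without_analyzer"`). Latent continuous maximal speeds are drawn
#' per sex, the without-analyzer speed as the with-analyzer speed minus a
#' paired shift; both are snapped to the protocol grid, and laps/times are
#' derived through the protocol arithmetic by placing the termination lap
#' uniformly inside the final stage. Measured VO2peak follows the linear
#' link `intercept + b_speed * speed_with + b_age * age + N(0, sd)`,
#' resampled into `vo2_bounds`. BMI and percent body fat are computed from
#' the sampled size and skinfold fields, never sampled.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @param n_girls,n_boys optional overrides of the per-sex counts.
#' @return long data frame, two rows per child, with columns `child_id`,
#'   `sex`, `age_y`, `height_cm`, `weight_kg`, `tri_mm`, `sub_mm`,
#'   `waist_cm`, `bmi`, `bmi_z`, `fat_pct`, `condition`, `max_speed_kmh`,
#'   `laps`, `time_s`, `vo2peak`, `hr_peak`, `rer`, `vt2`, `subjective`,
#'   plus the diagnostic column `latent_speed_kmh` (pre-snap speed, not
#'   written by [write_cohort()]).
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L,
                            n_girls = NULL, n_boys = NULL) {
  validate_params(params)
  if (!is.null(n_girls)) params$girls$n <- as.integer(n_girls)
  if (!is.null(n_boys)) params$boys$n <- as.integer(n_boys)
  validate_params(params)
  set.seed(as.integer(seed))
  ltab <- protocol_lap_table()
  out <- lapply(c(girls = "girls", boys = "boys"), function(sx) {
    generate_sex(params, sx, ltab)
  })
  coh <- rbind(out$girls, out$boys)
  rownames(coh) <- NULL
  coh
}

generate_sex <- function(params, sx, ltab) {
  b <- params[[sx]]
  n <- b$n
  rho <- params$correlations
  sex <- if (sx == "girls") "girl" else "boy"

  # (age, height, mass) share a fixed child-growth correlation structure;
  # sampling is on the z-scale so zero SDs degenerate cleanly to the mean
  R <- matrix(c(1, rho[["age_height"]], rho[["age_mass"]],
                rho[["age_height"]], 1, rho[["height_mass"]],
                rho[["age_mass"]], rho[["height_mass"]], 1), 3, 3)
  U <- chol(R)
  draw <- function(m) {
    z <- matrix(stats::rnorm(3 * m), m, 3) %*% U
    rs <- rho[["mass_skinfold"]]
    zc <- function() rs * z[, 3] + sqrt(1 - rs^2) * stats::rnorm(m)
    # mass, skinfolds and waist get lognormal marginals through a Gaussian
    # copula: published mean/SD are matched exactly on positive support
    data.frame(
      age_y = b$age[1] + b$age[2] * z[, 1],
      height_cm = b$height[1] + b$height[2] * z[, 2],
      weight_kg = lnorm_from_z(z[, 3], b$mass[1], b$mass[2]),
      tri_mm = lnorm_from_z(zc(), b$tri[1], b$tri[2]),
      sub_mm = lnorm_from_z(zc(), b$sub[1], b$sub[2]),
      waist_cm = lnorm_from_z(zc(), b$waist[1], b$waist[2]),
      bmi_z = b$bmi_z[1] + b$bmi_z[2] * stats::rnorm(m)
    )
  }
  kids <- draw(n)
  ok <- function(k) {
    k$age_y > 3 & k$height_cm > 80 & k$weight_kg > 10 &
      k$tri_mm > 0.5 & k$sub_mm > 0.5 & k$waist_cm > 30
  }
  for (i in 1:100) {
    bad <- !ok(kids)
    if (!any(bad)) break
    kids[bad, ] <- draw(sum(bad))
  }
  if (any(!ok(kids))) stop("could not sample physical children", call. = FALSE)

  kids$bmi <- bmi(kids$weight_kg, kids$height_cm)
  kids$fat_pct <- slaughter_fat_pct(kids$tri_mm, kids$sub_mm, sex)

  latent_with <- stats::rnorm(n, b$ms[1], b$ms[2])
  shift <- stats::rnorm(n, b$cond_shift[1], b$cond_shift[2])
  latent_without <- latent_with - shift
  sp_with <- snap_speed(latent_with)
  sp_without <- snap_speed(latent_without)

  trial_from_speed <- function(speed) {
    stage <- speed_to_stage(speed)
    vapply(stage, function(k) {
      in_stage <- ltab$lap[ltab$stage == k]
      if (!length(in_stage)) stop("protocol lap table too short", call. = FALSE)
      sample(in_stage, 1L)
    }, integer(1))
  }
  laps_with <- trial_from_speed(sp_with)
  laps_without <- trial_from_speed(sp_without)
  time_with <- ltab$cum_time[laps_with]
  time_without <- ltab$cum_time[laps_without]

  lk <- params$vo2_link
  vo2 <- lk[["intercept"]] + lk[["speed_slope"]] * sp_with +
    lk[["age_slope"]] * kids$age_y +
    stats::rnorm(n, 0, lk[["residual_sd"]])
  lo <- params$vo2_bounds[1]; hi <- params$vo2_bounds[2]
  for (i in 1:100) {
    bad <- vo2 < lo | vo2 > hi
    if (!any(bad)) break
    vo2[bad] <- lk[["intercept"]] + lk[["speed_slope"]] * sp_with[bad] +
      lk[["age_slope"]] * kids$age_y[bad] +
      stats::rnorm(sum(bad), 0, lk[["residual_sd"]])
  }
  vo2 <- pmin(pmax(vo2, lo), hi)

  hr <- pmin(pmax(stats::rnorm(n, b$hr[1], b$hr[2]), 61), 229)
  rer <- pmin(pmax(stats::rnorm(n, params$rer[1], params$rer[2]), 0.61), 1.59)
  vt2 <- stats::runif(n) < params$vt2_prob
  subjective <- stats::runif(n) < params$subjective_prob

  id <- sprintf("%s%03d", substr(sex, 1, 1), seq_len(n))
  one <- function(cond, speed, laps, time_s, latent) {
    data.frame(
      child_id = id, sex = sex,
      age_y = kids$age_y, height_cm = kids$height_cm,
      weight_kg = kids$weight_kg, tri_mm = kids$tri_mm,
      sub_mm = kids$sub_mm, waist_cm = kids$waist_cm,
      bmi = kids$bmi, bmi_z = kids$bmi_z, fat_pct = kids$fat_pct,
      condition = cond, max_speed_kmh = speed, laps = laps,
      time_s = time_s, vo2peak = vo2, hr_peak = hr, rer = rer,
      vt2 = vt2, subjective = subjective,
      latent_speed_kmh = latent,
      stringsAsFactors = FALSE
    )
  }
  d <- rbind(one("with_analyzer", sp_with, laps_with, time_with, latent_with),
             one("without_analyzer", sp_without, laps_without, time_without,
                 latent_without))
  d[order(d$child_id, d$condition), ]
}

COHORT_COLUMNS <- c("child_id", "sex", "age_y", "height_cm", "weight_kg",
                    "tri_mm", "sub_mm", "waist_cm", "bmi", "bmi_z",
                    "fat_pct", "condition", "max_speed_kmh", "laps",
                    "time_s", "vo2peak", "hr_peak", "rer", "vt2",
                    "subjective")

#' Write a cohort to CSV
#'
#' Writes the documented twenty-column cohort layout (diagnostic columns
#' such as `latent_speed_kmh` are dropped), in a fixed column order.
#'
#' @param cohort cohort data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing)) {
    stop("cohort lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(cohort[, COHORT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV path written by [write_cohort()] (or hand-built with the
#'   same header).
#' @return cohort data frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(COHORT_COLUMNS, names(d))
  if (length(missing)) {
    stop("cohort CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d$vt2 <- as.logical(d$vt2)
  d$subjective <- as.logical(d$subjective)
  d
}
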