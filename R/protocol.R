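# Deterministic arithmetic of the multistage 20-m shuttle run test (20mSRT).
#
# The test runs between lines 20 m apart to an accelerating beep cadence.
# The first stage is paced at 8.0 km/h and each subsequent one-minute stage
# adds 0.5 km/h. A lap is one 20-m shuttle; a lap belongs to the stage in
# which it starts (the pacing beep never changes mid-lap), so a lap run at
# v km/h lasts 72/v seconds (20 m at v/3.6 m/s).

SRT_START_SPEED <- 8.0
SRT_SPEED_INCREMENT <- 0.5
SRT_STAGE_SECONDS <- 60
SRT_LAP_METRES <- 20

#' Pacing speed of a 20mSRT stage
#'
#' @param stage 1-based stage index (vectorised).
#' @return speed in km/h: `8.0 + 0.5 * (stage - 1)`.
#' @export
#' @examples
#' stage_speed(1)      # 8.0
#' stage_speed(1:5)
stage_speed <- function(stage) {
  if (any(!is.finite(stage)) || any(stage < 1) || any(stage != floor(stage))) {
    stop("'stage' must be a positive integer (1-based)", call. = FALSE)
  }
  SRT_START_SPEED + SRT_SPEED_INCREMENT * (stage - 1)
}

#' Stage index for an on-grid shuttle speed
#'
#' Inverse of [stage_speed()]. Speeds must lie on the protocol grid
#' 8.0, 8.5, 9.0, ... km/h; a group mean such as 9.55 km/h is not a valid
#' individual final speed and is rejected.
#'
#' @param speed km/h, on the protocol grid (tolerance 1e-6).
#' @return 1-based stage index.
#' @export
speed_to_stage <- function(speed) {
  if (any(!is.finite(speed)) || any(speed < SRT_START_SPEED - 1e-6)) {
    stop("'speed' must be >= 8.0 km/h", call. = FALSE)
  }
  k <- (speed - SRT_START_SPEED) / SRT_SPEED_INCREMENT
  if (any(abs(k - round(k)) > 1e-6 / SRT_SPEED_INCREMENT)) {
    stop("'speed' is not on the 8.0 + 0.5k km/h protocol grid", call. = FALSE)
  }
  as.integer(round(k)) + 1L
}

#' Walk a lap count through the 20mSRT protocol
#'
#' Walks `total_laps` laps sequentially from time zero. Each lap is run at
#' the speed of the stage active at the lap's start (stage k occupies the
#' interval `[(k-1)*60, k*60)` seconds) and lasts `72 / speed` seconds.
#'
#' @param total_laps non-negative integer lap count.
#' @return A list of class `shuttle_outcome` with elements `total_laps`,
#'   `total_time` (s), `final_speed` (km/h) and `final_stage` (1-based).
#'   Zero laps gives time 0 in stage 1 at 8.0 km/h.
#' @export
#' @examples
#' laps_to_outcome(7)    # all of stage 1: 7 laps x 9 s = 63 s
#' laps_to_outcome(14)   # laps 8-14 at 8.5 km/h
laps_to_outcome <- function(total_laps) {
  if (length(total_laps) != 1L || !is.finite(total_laps) ||
      total_laps < 0 || total_laps != floor(total_laps)) {
    stop("'total_laps' must be a single non-negative integer", call. = FALSE)
  }
  t <- 0
  stage <- 1L
  if (total_laps > 0) {
    for (lap in seq_len(total_laps)) {
      stage <- as.integer(t %/% SRT_STAGE_SECONDS) + 1L
      t <- t + (SRT_LAP_METRES * 3.6) / stage_speed(stage)
    }
  }
  structure(
    list(total_laps = as.integer(total_laps),
         total_time = t,
         final_speed = stage_speed(stage),
         final_stage = stage),
    class = "shuttle_outcome"
  )
}

#' @export
print.shuttle_outcome <- function(x, ...) {
  cat(sprintf("20mSRT outcome: %d laps, %.2f s, final speed %.1f km/h (stage %d)\n",
              x$total_laps, x$total_time, x$final_speed, x$final_stage))
  invisible(x)
}

# Range of lap indices that start within a given stage, plus the cumulative
# lap count at that stage's end. Used by the cohort generator to place a
# child's termination lap inside their final stage.
stage_lap_range <- function(stage) {
  if (stage < 1 || stage != floor(stage)) {
    stop("'stage' must be a positive integer", call. = FALSE)
  }
  t <- 0
  lap <- 0L
  first <- NA_integer_
  last <- NA_integer_
  repeat {
    s <- as.integer(t %/% SRT_STAGE_SECONDS) + 1L
    if (s > stage) break
    lap <- lap + 1L
    if (s == stage && is.na(first)) first <- lap
    if (s == stage) last <- lap
    t <- t + (SRT_LAP_METRES * 3.6) / stage_speed(s)
  }
  list(first_lap = first, last_lap = last)
}
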