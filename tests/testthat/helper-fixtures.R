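# Shared fixtures built in code.

# published with-analyzer per-equation group means (mL/kg/min) used by the
# reproduction tests; names are equation ids
printed_means_with <- list(
  girls = c(`1` = 48.46, `2` = 42.84, `3` = 43.92, `4` = 45.60,
            `8` = 43.04, `9` = 33.01, `14` = 34.49, `15` = 44.15,
            `16` = 43.81, `17` = 43.61, `18` = 41.86, `19` = 35.81,
            `20` = 35.73, `21` = 45.76, `22` = 48.65),
  boys = c(`1` = 49.81, `2` = 47.01, `3` = 51.33, `4` = 51.71,
           `8` = 47.87, `9` = 36.82, `14` = 37.22, `15` = 46.18,
           `16` = 45.81, `17` = 45.39, `18` = 46.67, `19` = 43.97,
           `20` = 42.76, `21` = 50.26, `22` = 52.34)
)

# equations that are strictly linear in the sampled inputs (plug-in at the
# group means must reproduce the printed group mean to +/- 0.02); the
# interaction/rounding set reproduces to +/- 0.05
linear_eq_ids <- c(2, 3, 4, 8, 9, 14, 15, 17, 18, 19, 20)
interaction_eq_ids <- c(1, 21, 22)

# independent step-through oracle for the shuttle protocol: advance time in
# dt-second ticks; the lap speed is frozen at the stage active when the lap
# starts, and the lap ends on the first tick at which 20 m are covered
simulate_shuttle <- function(total_laps, dt = 0.01) {
  t <- 0
  speed <- 8.0
  for (lap in seq_len(total_laps)) {
    stage <- floor(t / 60) + 1
    speed <- 8.0 + 0.5 * (stage - 1)
    dist <- 0
    while (dist < 20 - 1e-12) {
      dist <- dist + speed / 3.6 * dt
      t <- t + dt
    }
  }
  list(total_time = t, final_speed = speed)
}

# a tiny deterministic child/trial pair carrying every input slot
full_child <- function(sex = "girl") {
  list(sex = sex, age_y = 8, height_cm = 130, weight_kg = 30,
       tri_mm = 10, sub_mm = 7, waist_cm = 57, bmi = 17.75,
       bmi_z = 0.5, fat_pct = 16)
}
full_trial <- function() {
  list(max_speed_kmh = 9.5, laps = 22, time_s = 180)
}
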