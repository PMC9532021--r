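# Shared fixtures. Unit tests run on a reduced geometry (196 px images at the
# study's angular extent) so maps and convolutions stay small; tests of the
# study conditions themselves (acceptance suite) use the default geometry.

small_geometry <- function() {
  geometry_spec(sampling_rate = 500, pixels_per_degree = 10,
                image_size_px = c(196L, 196L),
                image_extent_deg = c(19.6, 19.6),
                screen_size_px = c(480L, 270L))
}

# a recording with explicit sample coordinates (defaults: all valid, 4 s grid)
make_recording <- function(x, y, valid = TRUE, geometry = small_geometry(),
                           participant_id = "p1", group = "SC",
                           image_id = "imgA", trial_index = 1L, block = 1L,
                           order = 1L, check = FALSE) {
  n <- length(x)
  samples <- tibble::tibble(
    t = (seq_len(n) - 1) / geometry$sampling_rate,
    x = x, y = rep_len(y, n), valid = rep_len(valid, n)
  )
  gaze_recording(participant_id, group, image_id, trial_index, block,
                 samples, geometry, order = order, check = check)
}

# full-length recording whose valid samples sit at given points (recycled)
make_recording_4s <- function(x, y, geometry = small_geometry(), ...) {
  n <- round(4 * geometry$sampling_rate)
  make_recording(rep_len(x, n), rep_len(y, n), geometry = geometry,
                 check = TRUE, ...)
}

# uniform predictor map on a geometry
uniform_map <- function(geometry = small_geometry()) {
  w <- geometry$image_size_px[1]; h <- geometry$image_size_px[2]
  freegaze:::new_predictor_map(matrix(1, h, w), geometry, "external")
}

# single-Gaussian bump map centred at (cx, cy) px
bump_map <- function(cx, cy, sigma_px = 15, geometry = small_geometry()) {
  w <- geometry$image_size_px[1]; h <- geometry$image_size_px[2]
  gx <- dnorm(seq_len(w) - 0.5, cx, sigma_px)
  gy <- dnorm(seq_len(h) - 0.5, cy, sigma_px)
  freegaze:::new_predictor_map(gy %o% gx, geometry, "external")
}

# brute-force AUC oracle: proportion of favourable pairs with half-credit ties
auc_bruteforce <- function(gazed, nongazed) {
  cmp <- outer(gazed, nongazed, ">") + 0.5 * outer(gazed, nongazed, "==")
  mean(cmp)
}

# small synthetic cohort on the reduced geometry (2 participants per group)
small_cohort_spec <- function(geometry = small_geometry(), n_per_group = 2,
                              ...) {
  cohort_spec(
    groups = list(
      CC = group_profile(n_per_group, "multiplanar_irregular",
                         nystagmus_amplitude_deg = 3,
                         nystagmus_frequency_hz = 3,
                         slow_phase_accel = 2.5, fixation_mean_ms = 600,
                         missing_rate = 0.10,
                         acuity_range = c(0.5, 1.4)),
      SC = group_profile(n_per_group, "fixation_saccade",
                         missing_rate = 0.037, acuity_range = c(0, 0.2)),
      DC = group_profile(n_per_group, "fixation_saccade",
                         missing_rate = 0.043, acuity_range = c(0.2, 0.8)),
      NC = group_profile(n_per_group, "horizontal_jerk",
                         nystagmus_amplitude_deg = 4,
                         nystagmus_frequency_hz = 4,
                         slow_phase_accel = 2.5, fixation_mean_ms = 600,
                         missing_rate = 0.10,
                         acuity_range = c(0.1, 0.6))
    ),
    geometry = geometry, ...
  )
}

# long-format frame with planted per-group slopes over a covariate
make_interaction_frame <- function(seed, slopes = c(g1 = 0, g2 = -0.02),
                                   n_per_group = 10, n_cov = 7,
                                   sd_noise = 0.02, sd_intercept = 0.02) {
  set.seed(seed)
  rows <- list()
  for (g in names(slopes)) {
    for (p in seq_len(n_per_group)) {
      b0 <- 0.6 + rnorm(1, 0, sd_intercept)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = paste0(g, p), group = g,
        interval = seq_len(n_cov),
        y = b0 + slopes[[g]] * seq_len(n_cov) + rnorm(n_cov, 0, sd_noise)
      )
    }
  }
  do.call(rbind, rows)
}
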