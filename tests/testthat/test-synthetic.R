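test_that("task events are load-balanced, correctly timed and deterministic", {
  cfg <- task_config(visible_targets = c(2, 4, 6, 8), min_sequences = 24)
  ev <- generate_task_events(cfg, seed = 3)
  expect_true(all(table(ev$target_id) == 6))
  expect_setequal(unique(ev$target_id), c(2, 4, 6, 8))
  # successive outer-target onsets separated by at least display + cue + hold
  expect_true(all(diff(ev$target_on_s) >=
                    cfg$target_display_s + cfg$cue_s + cfg$center_hold_s - 1e-9))
  expect_true(all(abs(ev$target_on_s - ev$cue_on_s - cfg$cue_s) < 1e-9))
  expect_identical(ev, generate_task_events(cfg, seed = 3))
  expect_false(identical(ev$target_id,
                         generate_task_events(cfg, seed = 4)$target_id))
})

test_that("task config rejects invalid target subsets", {
  expect_error(task_config(visible_targets = integer(0)))
  expect_error(task_config(visible_targets = 9))
  expect_error(task_config(radius = -1))
})

test_that("noiseless trajectories follow the minimum-jerk speed law", {
  cl <- clean_session()
  gt <- cl$gt
  # analytic peak speed 1.875 * distance / duration, measured per reach
  for (k in sample(nrow(gt), 8)) {
    idx <- cl$f0$t >= gt$t_onset[k] & cl$f0$t <= gt$t_offset[k]
    d <- sqrt((gt$to_x[k] - gt$from_x[k])^2 + (gt$to_y[k] - gt$from_y[k])^2 +
                (gt$to_z[k] - gt$from_z[k])^2)
    expect_equal(max(cl$f0$speed[idx]), 1.875 * d / gt$duration[k],
                 tolerance = 0.01)
  }
  # 178 mm in 0.8 s peaks near 417 mm/s
  expect_equal(1.875 * 178 / 0.8, 417.2, tolerance = 1e-3)
})

test_that("trajectory validity, continuity and error handling behave", {
  cl <- clean_session()
  expect_true(all(cl$traj$valid))
  # position continuous across hold/reach boundaries (max step bounded by
  # peak speed / frame rate)
  step <- sqrt(rowSums(diff(attr(cl$traj, "pos_clean"))^2))
  expect_lt(max(step), 600 / 120)
  expect_error(motor_params(tremor_amplitude_mm = 1, tremor_freq_hz = 0))
  expect_error(motor_params(tremor_amplitude_mm = 1, tremor_freq_hz = 80))
})

test_that("sessions are bit-identical under a fixed seed and units have
           independent streams", {
  cfg <- task_config(visible_targets = c(1, 5), min_sequences = 4)
  units <- list(unit_ground_truth(1L), unit_ground_truth(2L))
  s1 <- simulate_session(cfg, motor_params(), units, seed = 11)
  s2 <- simulate_session(cfg, motor_params(), units, seed = 11)
  expect_identical(s1$trajectory$pos, s2$trajectory$pos)
  expect_identical(s1$spikes, s2$spikes)
  # adding a unit must not perturb existing units' spike trains
  s3 <- simulate_session(cfg, motor_params(),
                         c(units, list(unit_ground_truth(3L))), seed = 11)
  expect_identical(s1$spikes[["1"]], s3$spikes[["1"]])
  expect_identical(s1$spikes[["2"]], s3$spikes[["2"]])
})

test_that("homogeneous Poisson spike counts match rate x duration", {
  s <- std_session()
  dur <- diff(s$span)
  st <- generate_spikes(s$traj, unit_ground_truth(9L, baseline_rate = 20),
                        seed = 2)
  expected <- 20 * dur
  expect_lt(abs(length(st) - expected), 4 * sqrt(expected))
  expect_true(all(st >= s$span[1] & st <= s$span[2]))
  expect_identical(st, generate_spikes(
    s$traj, unit_ground_truth(9L, baseline_rate = 20), seed = 2))
  expect_error(generate_spikes(s$traj, unit_ground_truth(1, baseline_rate = -1)))
})

test_that("rate conservation holds for drifting modulated units", {
  s <- std_session()
  u <- unit_ground_truth(10L, baseline_rate = 25,
                         weights = c(speed = 3), drift_amplitude = 0.3,
                         drift_period_s = 60)
  st <- generate_spikes(s$traj, u, seed = 3, features = s$feats)
  # realized count within Monte-Carlo error of the time-averaged rate
  # (conservatively bounded: the true mean rate differs from baseline by the
  # rectification and drift terms, both small here)
  expect_lt(abs(length(st) / diff(s$span) - 25), 3)
})

test_that("spike-triggered average velocity peaks at the coupled lag", {
  s <- std_session()
  u <- unit_ground_truth(11L, baseline_rate = 20,
                         weights = c(vel_x = 12), true_lag_ms = 100)
  st <- generate_spikes(s$traj, u, seed = 4, features = s$feats)
  offsets <- seq(-0.4, 0.4, by = 1 / 120)
  sta <- vapply(offsets, function(o)
    mean(approx(s$traj$t, s$feats[, "vel_x"], xout = st + o, rule = 2)$y),
    numeric(1))
  # rate at t reflects velocity at t - lag, so the STA of velocity at
  # spike-time + offset peaks at offset = -lag
  expect_lt(abs(offsets[which.max(sta)] + 0.1), 0.03)
})

test_that("session bundles round-trip through disk", {
  cfg <- task_config(visible_targets = c(1, 5), min_sequences = 4)
  ses <- simulate_session(cfg, motor_params(),
                          list(unit_ground_truth(1L)), seed = 11)
  dir <- withr::local_tempdir()
  write_session_bundle(ses, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "events.csv", "kinematics.csv", "spikes.csv", "ground_truth.json",
    "config.yaml")))))
  back <- read_session_bundle(dir)
  expect_equal(back$events$target_on_s, ses$events$target_on_s)
  expect_equal(back$trajectory$pos[, 1], ses$trajectory$pos[, 1],
               tolerance = 1e-12)
  expect_equal(back$spikes[["1"]], ses$spikes[["1"]], tolerance = 1e-12)
  expect_equal(back$config$radius, 178)
})
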