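# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# a standard 4-target session (24 sequences, 48 reaches) with default motor
# behavior, plus derived features / curated reaches / regression design
std_session <- function() {
  if (is.null(.fixtures$std)) {
    cfg <- task_config(visible_targets = c(1, 3, 5, 7), min_sequences = 24)
    ses <- simulate_session(cfg, motor_params(),
                            list(unit_ground_truth(1L)), seed = 5)
    traj <- ses$trajectory
    f0 <- compute_features(traj, 0)
    f15 <- compute_features(traj, 15)
    f50 <- compute_features(traj, 50)
    reaches <- curate_reaches(detect_reaches(f0, ses$events, cfg))
    .fixtures$std <- list(
      cfg = cfg, ses = ses, traj = traj, span = range(traj$t),
      gt = attr(traj, "ground_truth"), f0 = f0, f15 = f15, f50 = f50,
      reaches = reaches, design = build_design(f15, reaches),
      feats = vimreach:::synthetic_feature_matrix(traj,
                                                  attr(traj, "ground_truth"))
    )
  }
  .fixtures$std
}

# noiseless minimum-jerk session (no tremor / noise / dropped frames)
clean_session <- function() {
  if (is.null(.fixtures$clean)) {
    cfg <- task_config(visible_targets = 1:8, min_sequences = 24)
    mot <- motor_params(tremor_amplitude_mm = 0, pos_noise_sd_mm = 0,
                        dropped_frame_prob = 0)
    ev <- generate_task_events(cfg, seed = 1)
    traj <- generate_trajectory(ev, cfg, mot, seed = 1)
    .fixtures$clean <- list(cfg = cfg, mot = mot, ev = ev, traj = traj,
                            gt = attr(traj, "ground_truth"),
                            f0 = compute_features(traj, 0))
  }
  .fixtures$clean
}

# smoothed + z-scored rate function for a spike train of the std session
std_rate <- function(spikes, kernel_ms, zscore = FALSE, id = NA) {
  s <- std_session()
  r <- smooth_rate(fractional_interval_rate(spikes, s$span, id), kernel_ms)
  if (zscore) r <- sliding_zscore(r) else r
}

# inhomogeneous-Poisson spike train for an arbitrary rate curve given on the
# trajectory frame grid (test-side generator, independent of generate_spikes)
thin_spikes <- function(t, rate, seed) {
  set.seed(seed)
  rmax <- max(rate)
  n <- rpois(1, rmax * diff(range(t)))
  cand <- sort(runif(n, min(t), max(t)))
  keep <- runif(n) < approx(t, rate, xout = cand)$y / rmax
  unique(cand[keep])
}

# a trajectory_series built directly from a position matrix
make_traj <- function(t, pos, valid = rep(TRUE, length(t)), fps = 120) {
  structure(list(t = t, pos = pos, valid = valid, fps = fps),
            class = "trajectory_series")
}
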