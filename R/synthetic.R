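#' Task configuration for the center-out-and-back reaching paradigm
#'
#' Describes the behavioral task: a central target plus `n_targets` outer
#' targets evenly spaced on a circle of radius `radius` mm in the display
#' plane. Each trial shows the central target for `center_hold_s` seconds,
#' then overlays a directional cue for `cue_s` seconds, then shows one outer
#' target for `target_display_s` seconds; its disappearance (center
#' re-display) is the return cue. Outer targets are drawn in a load-balanced
#' pseudorandom order, cycling through `visible_targets` until at least
#' `min_sequences` out-and-back sequences have been presented.
#'
#' @param n_targets number of outer targets (default 8).
#' @param radius circle radius in mm (default 178).
#' @param target_diameter target diameter in mm (default 30).
#' @param center_hold_s central-target display duration in s (default 3).
#' @param target_display_s outer-target display duration in s (default 3).
#' @param cue_s directional-cue duration in s (default 0.7).
#' @param min_sequences minimum number of out-and-back sequences (default 24).
#' @param visible_targets integer ids of the targets visible to the subject
#'   (default all).
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_targets = 8L, radius = 178, target_diameter = 30,
                        center_hold_s = 3, target_display_s = 3, cue_s = 0.7,
                        min_sequences = 24L,
                        visible_targets = seq_len(n_targets)) {
  stopifnot(radius > 0, n_targets >= 1, min_sequences >= 1)
  visible_targets <- as.integer(visible_targets)
  if (length(visible_targets) < 1 || length(visible_targets) > n_targets ||
      any(visible_targets < 1) || any(visible_targets > n_targets)) {
    stop("visible_targets must be a non-empty subset of 1..n_targets")
  }
  structure(list(
    n_targets = as.integer(n_targets), radius = radius,
    target_diameter = target_diameter, center_hold_s = center_hold_s,
    target_display_s = target_display_s, cue_s = cue_s,
    min_sequences = as.integer(min_sequences),
    visible_targets = visible_targets
  ), class = "task_config")
}

#' Outer target positions in mm
#'
#' Targets lie in the display plane (z = 0), numbered counterclockwise with
#' target 4 at the upper right and target 8 (its diametric opposite) at the
#' lower left for the default 8-target layout.
#'
#' @param config a [task_config()].
#' @return n_targets x 3 matrix of positions (x rightward, y upward, z toward
#'   the subject); the central target is at the origin.
#' @export
target_positions <- function(config) {
  k <- seq_len(config$n_targets)
  ang <- (k - 3) * 2 * pi / config$n_targets
  cbind(x = config$radius * cos(ang), y = config$radius * sin(ang), z = 0)
}

#' Generate the task event table
#'
#' Outer targets are presented in load-balanced pseudorandom order: complete
#' cycles through all visible targets, the order permuted independently within
#' each cycle, until at least `min_sequences` trials are scheduled.
#'
#' @param config a [task_config()].
#' @param seed integer seed.
#' @param t0 time of the first trial start in s (default 1).
#' @return data.frame with columns trial, target_id, cue_on_s, target_on_s.
#' @export
generate_task_events <- function(config, seed = 1L, t0 = 1) {
  if (length(config$visible_targets) == 0) stop("no visible targets")
  set.seed(derive_seed(seed, 1L))
  vis <- config$visible_targets
  n_cycles <- ceiling(config$min_sequences / length(vis))
  order_ids <- unlist(lapply(seq_len(n_cycles), function(i) sample(vis)))
  n_trials <- length(order_ids)
  trial_len <- config$center_hold_s + config$cue_s + config$target_display_s
  start <- t0 + (seq_len(n_trials) - 1) * trial_len
  data.frame(
    trial = seq_len(n_trials),
    target_id = order_ids,
    cue_on_s = start + config$center_hold_s,
    target_on_s = start + config$center_hold_s + config$cue_s
  )
}

#' Motor behavior parameters for the trajectory generator
#'
#' @param reach_duration_median_s median reach duration (lognormal), s.
#' @param reach_duration_sdlog lognormal sd of reach durations.
#' @param reaction_time_range_s uniform reaction-time range after the go cue, s.
#' @param tremor_amplitude_mm peak tremor displacement, mm.
#' @param tremor_freq_hz center tremor frequency, Hz (essential-tremor band
#'   4-12 Hz).
#' @param tremor_coherence_s phase coherence time of the tremor oscillation,
#'   s: the instantaneous phase diffuses so the autocorrelation of the
#'   oscillation decays with this time constant, emulating the quasi-periodic
#'   (frequency-wandering) character of physiological tremor. `Inf` gives a
#'   pure sinusoid.
#' @param tremor_during_movement if TRUE the tremor continues through reaches
#'   (action tremor, the clinical hallmark of essential tremor); by default it
#'   is applied during holds only, ramped in and out smoothly so position
#'   stays continuous.
#' @param pos_noise_sd_mm sd of additive white positional tracking noise, mm.
#' @param dropped_frame_prob per-frame probability of a dropped (invalid) frame.
#' @param fps video frame rate, frames/s.
#' @return an object of class `motor_params`.
#' @export
motor_params <- function(reach_duration_median_s = 0.8,
                         reach_duration_sdlog = 0.15,
                         reaction_time_range_s = c(0.15, 0.4),
                         tremor_amplitude_mm = 1.5,
                         tremor_freq_hz = 5,
                         tremor_coherence_s = 1.5,
                         tremor_during_movement = FALSE,
                         pos_noise_sd_mm = 0.3,
                         dropped_frame_prob = 0.01,
                         fps = 120) {
  stopifnot(reach_duration_median_s > 0, fps > 0)
  if (tremor_amplitude_mm > 0) {
    if (tremor_freq_hz <= 0) stop("tremor frequency must be positive")
    if (tremor_freq_hz >= fps / 2) {
      stop("tremor frequency exceeds the Nyquist limit for the frame rate")
    }
  }
  structure(list(
    reach_duration_median_s = reach_duration_median_s,
    reach_duration_sdlog = reach_duration_sdlog,
    reaction_time_range_s = reaction_time_range_s,
    tremor_amplitude_mm = tremor_amplitude_mm,
    tremor_freq_hz = tremor_freq_hz,
    tremor_coherence_s = tremor_coherence_s,
    tremor_during_movement = tremor_during_movement,
    pos_noise_sd_mm = pos_noise_sd_mm,
    dropped_frame_prob = dropped_frame_prob,
    fps = fps
  ), class = "motor_params")
}

#' Minimum-jerk position profile
#'
#' Normalized minimum-jerk displacement s(tau) = 10 tau^3 - 15 tau^4 +
#' 6 tau^5 for tau in [0, 1]; its speed peaks at 1.875 * distance / duration
#' at the movement midpoint.
#'
#' @param tau normalized time, clipped to [0, 1].
#' @return normalized displacement in [0, 1].
#' @export
min_jerk_profile <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

#' Generate a fingertip trajectory for a task event table
#'
#' Builds a piecewise trajectory: stationary holds over the currently active
#' target with optional additive tremor sinusoid and white tracking noise, and
#' point-to-point minimum-jerk segments between hold positions. Each trial
#' contains an outward reach (after the outer-target onset plus a reaction
#' time) and an inward return reach (after the outer-target offset). Dropped
#' frames are flagged invalid with NA positions. Ground-truth reach onsets,
#' offsets and directions are recorded in the `ground_truth` attribute.
#'
#' @param events event table from [generate_task_events()].
#' @param config the [task_config()] used to generate `events`.
#' @param motor a [motor_params()] object.
#' @param seed integer seed.
#' @return a `trajectory_series`: list(t, pos, valid, fps) where pos is an
#'   n x 3 matrix in mm; attribute `ground_truth` holds the true reach table
#'   and `pos_clean` the noise-free positions (tremor included, tracking
#'   noise and dropped frames excluded).
#' @export
generate_trajectory <- function(events, config, motor = motor_params(),
                                seed = 1L) {
  set.seed(derive_seed(seed, 2L))
  tp <- target_positions(config)
  n_trials <- nrow(events)
  rt <- function() stats::runif(1, motor$reaction_time_range_s[1],
                                motor$reaction_time_range_s[2])
  dur <- function() stats::rlnorm(1, log(motor$reach_duration_median_s),
                                  motor$reach_duration_sdlog)

  gt <- vector("list", 2L * n_trials)
  for (i in seq_len(n_trials)) {
    tid <- events$target_id[i]
    t_go_out <- events$target_on_s[i]
    t_go_in <- events$target_on_s[i] + config$target_display_s
    d_out <- dur(); d_in <- dur()
    on_out <- t_go_out + rt()
    on_in <- t_go_in + rt()
    gt[[2 * i - 1]] <- data.frame(
      trial = i, target_id = tid, outward = TRUE, t_go = t_go_out,
      t_onset = on_out, t_offset = on_out + d_out, duration = d_out,
      from_x = 0, from_y = 0, from_z = 0,
      to_x = tp[tid, 1], to_y = tp[tid, 2], to_z = tp[tid, 3])
    gt[[2 * i]] <- data.frame(
      trial = i, target_id = tid, outward = FALSE, t_go = t_go_in,
      t_onset = on_in, t_offset = on_in + d_in, duration = d_in,
      from_x = tp[tid, 1], from_y = tp[tid, 2], from_z = tp[tid, 3],
      to_x = 0, to_y = 0, to_z = 0)
  }
  gt <- do.call(rbind, gt)
  gt$peak_speed <- 1.875 *
    sqrt((gt$to_x - gt$from_x)^2 + (gt$to_y - gt$from_y)^2 +
           (gt$to_z - gt$from_z)^2) / gt$duration

  t_end <- max(gt$t_offset) + 3
  t <- seq(0, t_end, by = 1 / motor$fps)
  n <- length(t)

  # piecewise position: hold at 'from' before each reach, min-jerk inside it,
  # hold at 'to' afterwards
  pos <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  seg <- findInterval(t, gt$t_onset) # 0 = before first reach
  for (k in seq_len(nrow(gt))) {
    idx <- which(seg == k)
    if (!length(idx)) next
    tau <- (t[idx] - gt$t_onset[k]) / gt$duration[k]
    s <- min_jerk_profile(tau)
    from <- c(gt$from_x[k], gt$from_y[k], gt$from_z[k])
    to <- c(gt$to_x[k], gt$to_y[k], gt$to_z[k])
    pos[idx, ] <- rep(from, each = length(idx)) +
      outer(s, to - from)
  }

  # tremor: sinusoid along a fixed random 3D direction, amplitude ramped to
  # zero inside reaches unless tremor_during_movement
  if (motor$tremor_amplitude_mm > 0) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    phase <- stats::runif(1, 0, 2 * pi) + 2 * pi * motor$tremor_freq_hz * t
    coh <- motor$tremor_coherence_s %||% Inf
    if (is.finite(coh) && coh > 0) {
      # phase diffusion: autocorrelation of the oscillation decays as
      # exp(-t / coherence) (Wiener phase with variance 2t / coherence)
      dphi <- stats::rnorm(n, 0, sqrt(2 * (1 / motor$fps) / coh))
      phase <- phase + cumsum(dphi)
    }
    wave <- motor$tremor_amplitude_mm * sin(phase)
    env <- rep(1, n)
    if (!motor$tremor_during_movement) {
      # raised-cosine fade inside the holds: zero amplitude and zero slope at
      # the hold/reach boundaries, full amplitude beyond `ramp` into the hold
      ramp <- 0.15
      dist_in <- rep(Inf, n)
      for (k in seq_len(nrow(gt))) {
        inside <- t >= gt$t_onset[k] & t <= gt$t_offset[k]
        dist_in[inside] <- 0
        d <- pmin(abs(t - gt$t_onset[k]), abs(t - gt$t_offset[k]))
        dist_in <- pmin(dist_in, ifelse(inside, 0, d))
      }
      env <- sin(pi / 2 * pmin(1, dist_in / ramp))^2
    }
    pos <- pos + outer(wave * env, u)
  }
  pos_clean <- pos

  if (motor$pos_noise_sd_mm > 0) {
    pos <- pos + matrix(stats::rnorm(3 * n, 0, motor$pos_noise_sd_mm), n, 3)
  }
  valid <- rep(TRUE, n)
  if (motor$dropped_frame_prob > 0) {
    valid <- stats::runif(n) >= motor$dropped_frame_prob
    pos[!valid, ] <- NA_real_
  }

  structure(
    list(t = t, pos = pos, valid = valid, fps = motor$fps),
    ground_truth = gt, pos_clean = pos_clean,
    class = "trajectory_series")
}

#' Ground-truth parameters of one synthetic spiking unit
#'
#' Defines the true rate function
#' rate(t) = drift(t) * max(0, baseline + sum_f w_f * z_f(t - lag) + dir(t)),
#' where z_f are session-z-scored kinematic/error features, lag is the
#' neural-to-kinematic lag (positive = neural activity follows kinematics),
#' and dir(t) = direction_gain * <reach direction, preferred direction>
#' during reaches.
#'
#' @param unit_id integer unit identifier.
#' @param baseline_rate baseline firing rate, spikes/s (> 0).
#' @param weights named numeric vector of coupling weights in spikes/s per
#'   z-scored feature unit; names from: pos_x, pos_y, pos_z, vel_x, vel_y,
#'   vel_z, speed, acc_x, acc_y, acc_z, acc_mag, acc_signed, err_x, err_y,
#'   err_z, err_mag.
#' @param direction_gain spikes/s at a reach parallel to `preferred_direction`.
#' @param preferred_direction 3-vector, normalized internally.
#' @param true_lag_ms signed neural-to-kinematic lag in ms.
#' @param drift_amplitude relative amplitude of a slow sinusoidal
#'   multiplicative gain (0 = no drift).
#' @param drift_period_s period of the drift sinusoid, s.
#' @return an object of class `unit_ground_truth`.
#' @export
unit_ground_truth <- function(unit_id, baseline_rate = 20, weights = NULL,
                              direction_gain = 0,
                              preferred_direction = c(1, 0, 0),
                              true_lag_ms = 0, drift_amplitude = 0,
                              drift_period_s = 120) {
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  allowed <- c("pos_x", "pos_y", "pos_z", "vel_x", "vel_y", "vel_z", "speed",
               "acc_x", "acc_y", "acc_z", "acc_mag", "acc_signed",
               "err_x", "err_y", "err_z", "err_mag")
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(names(weights) %in% allowed)) {
      stop("weights must be named with feature column names")
    }
  }
  pd <- preferred_direction / sqrt(sum(preferred_direction^2))
  structure(list(
    unit_id = as.integer(unit_id), baseline_rate = baseline_rate,
    weights = weights, direction_gain = direction_gain,
    preferred_direction = pd, true_lag_ms = true_lag_ms,
    drift_amplitude = drift_amplitude, drift_period_s = drift_period_s
  ), class = "unit_ground_truth")
}

# z-scored ground-truth feature matrix at the trajectory frame times,
# including per-reach error columns (position minus reach endpoint, defined
# during a window around each reach, zero elsewhere)
synthetic_feature_matrix <- function(traj, gt_reaches) {
  clean <- attr(traj, "pos_clean")
  ct <- structure(list(t = traj$t, pos = clean,
                       valid = rep(TRUE, length(traj$t)), fps = traj$fps),
                  class = "trajectory_series")
  sm <- interpolate_and_smooth(ct, kernel_sd_ms = 15)
  kf <- differentiate(sm)
  err <- matrix(0, nrow(kf), 3)
  for (k in seq_len(nrow(gt_reaches))) {
    idx <- which(kf$t >= gt_reaches$t_onset[k] - 0.25 &
                   kf$t <= gt_reaches$t_offset[k] + 0.25)
    endp <- c(gt_reaches$to_x[k], gt_reaches$to_y[k], gt_reaches$to_z[k])
    err[idx, ] <- cbind(kf$pos_x[idx] - endp[1], kf$pos_y[idx] - endp[2],
                        kf$pos_z[idx] - endp[3])
  }
  f <- cbind(pos_x = kf$pos_x, pos_y = kf$pos_y, pos_z = kf$pos_z,
             vel_x = kf$vel_x, vel_y = kf$vel_y, vel_z = kf$vel_z,
             speed = kf$speed,
             acc_x = kf$acc_x, acc_y = kf$acc_y, acc_z = kf$acc_z,
             acc_mag = kf$acc_mag, acc_signed = kf$acc_signed,
             err_x = err[, 1], err_y = err[, 2], err_z = err[, 3],
             err_mag = sqrt(rowSums(err^2)))
  scale(f)
}

#' Simulate spike times for one unit by Poisson thinning
#'
#' The unit's rate function is assembled on the kinematic frame grid from the
#' z-scored ground-truth features (evaluated at t - lag), the direction term,
#' and the slow drift gain, clipped at zero, then sampled with an
#' inhomogeneous-Poisson thinning scheme.
#'
#' @param traj a `trajectory_series` from [generate_trajectory()].
#' @param unit a [unit_ground_truth()].
#' @param seed integer seed.
#' @param features optional precomputed feature matrix from the generator
#'   (recomputed from `traj` when NULL).
#' @return numeric vector of spike times in s.
#' @export
generate_spikes <- function(traj, unit, seed = 1L, features = NULL) {
  if (unit$baseline_rate <= 0) stop("baseline_rate must be positive")
  gt <- attr(traj, "ground_truth")
  t <- traj$t
  fps <- traj$fps
  rate <- rep(unit$baseline_rate, length(t))

  if (!is.null(unit$weights) && length(unit$weights)) {
    if (is.null(features)) features <- synthetic_feature_matrix(traj, gt)
    shift <- unit$true_lag_ms / 1000
    for (nm in names(unit$weights)) {
      # rate at time t reflects the feature at t - lag
      fshift <- stats::approx(t + shift, features[, nm], xout = t,
                              rule = 2)$y
      rate <- rate + unit$weights[[nm]] * fshift
    }
  }
  if (unit$direction_gain != 0 && !is.null(gt)) {
    for (k in seq_len(nrow(gt))) {
      u <- c(gt$to_x[k] - gt$from_x[k], gt$to_y[k] - gt$from_y[k],
             gt$to_z[k] - gt$from_z[k])
      u <- u / sqrt(sum(u^2))
      idx <- which(t >= gt$t_onset[k] + unit$true_lag_ms / 1000 &
                     t <= gt$t_offset[k] + unit$true_lag_ms / 1000)
      rate[idx] <- rate[idx] +
        unit$direction_gain * sum(u * unit$preferred_direction)
    }
  }
  rate <- pmax(rate, 0)
  if (unit$drift_amplitude != 0) {
    rate <- rate * (1 + unit$drift_amplitude *
                      sin(2 * pi * t / unit$drift_period_s))
    rate <- pmax(rate, 0)
  }

  set.seed(derive_seed(seed, 100L + unit$unit_id))
  span <- range(t)
  rmax <- max(rate)
  if (rmax <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, rmax * diff(span))
  # unique(): the RNG grid can produce coincident candidates at this n, and
  # a physical unit cannot fire two spikes at the same instant
  cand <- unique(sort(stats::runif(n_cand, span[1], span[2])))
  r_at <- stats::approx(t, rate, xout = cand, rule = 2)$y
  keep <- stats::runif(length(cand)) < r_at / rmax
  cand[keep]
}

#' Simulate a complete synthetic session
#'
#' Generates the task event table, the fingertip trajectory and one spike
#' train per unit, all from a single master seed (per-stage and per-unit
#' streams are derived by fixed offsets so adding a unit does not perturb the
#' others).
#'
#' @param config a [task_config()].
#' @param motor a [motor_params()].
#' @param units list of [unit_ground_truth()] objects.
#' @param seed master integer seed.
#' @return an object of class `synthetic_session`: list(config, motor, events,
#'   trajectory, spikes [named list], units, ground_truth, seed).
#' @export
simulate_session <- function(config = task_config(), motor = motor_params(),
                             units = list(unit_ground_truth(1L)), seed = 1L) {
  events <- generate_task_events(config, seed = seed)
  traj <- generate_trajectory(events, config, motor, seed = seed)
  gt <- attr(traj, "ground_truth")
  feats <- NULL
  needs_feats <- any(vapply(units, function(u)
    !is.null(u$weights) && length(u$weights) > 0, logical(1)))
  if (needs_feats) feats <- synthetic_feature_matrix(traj, gt)
  spikes <- lapply(units, function(u)
    generate_spikes(traj, u, seed = seed, features = feats))
  names(spikes) <- vapply(units, function(u) as.character(u$unit_id),
                          character(1))
  structure(list(
    config = config, motor = motor, events = events, trajectory = traj,
    spikes = spikes, units = units, ground_truth = gt, seed = seed
  ), class = "synthetic_session")
}

#' Write a session bundle to disk
#'
#' Writes `events.csv`, `kinematics.csv`, `spikes.csv`, `ground_truth.json`
#' and `config.yaml` into `dir`. All times are seconds from recording start;
#' positions are mm.
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  traj <- session$trajectory
  kin <- data.frame(t_s = traj$t, x_mm = traj$pos[, 1], y_mm = traj$pos[, 2],
                    z_mm = traj$pos[, 3], valid = traj$valid)
  utils::write.csv(kin, file.path(dir, "kinematics.csv"), row.names = FALSE)
  sp <- do.call(rbind, lapply(names(session$spikes), function(u)
    if (length(session$spikes[[u]]))
      data.frame(unit_id = as.integer(u), t_s = session$spikes[[u]])))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  gt <- list(
    seed = session$seed,
    reaches = session$ground_truth,
    units = lapply(session$units, function(u) {
      u$weights <- as.list(u$weights)
      unclass(u)
    })
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- c(unclass(session$config), unclass(session$motor))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 15)
  invisible(dir)
}

#' Read a session bundle from disk
#'
#' @param dir directory containing `events.csv`, `kinematics.csv` and
#'   `spikes.csv` (plus optional `ground_truth.json`, `config.yaml`).
#' @return list(events, trajectory, spikes, config, ground_truth); missing
#'   optional files yield NULL entries.
#' @export
read_session_bundle <- function(dir) {
  events <- utils::read.csv(file.path(dir, "events.csv"))
  kin <- utils::read.csv(file.path(dir, "kinematics.csv"))
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  dt <- stats::median(diff(kin$t_s))
  traj <- structure(list(
    t = kin$t_s,
    pos = cbind(x = kin$x_mm, y = kin$y_mm, z = kin$z_mm),
    valid = as.logical(kin$valid), fps = 1 / dt
  ), class = "trajectory_series")
  spikes <- split(sp$t_s, sp$unit_id)
  cfg_path <- file.path(dir, "config.yaml")
  gt_path <- file.path(dir, "ground_truth.json")
  list(
    events = events, trajectory = traj, spikes = spikes,
    config = if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL,
    ground_truth = if (file.exists(gt_path))
      jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  )
}
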