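#' Zero-phase low-pass filter for reach detection
#'
#' 4th-order Butterworth applied forward and backward (zero phase, so event
#' timing is preserved), with the cutoff chosen below the essential-tremor
#' band (4-12 Hz) so tremor does not contaminate peak picking.
#'
#' @param x numeric signal sampled at `fs` Hz.
#' @param cutoff_hz cutoff frequency (default 3).
#' @param fs sampling rate, Hz.
#' @param order filter order (default 4).
#' @return filtered signal, same length.
#' @keywords internal
lowpass_zero_phase <- function(x, cutoff_hz = 3, fs = 120, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# precompute the filtered (peak picking, direction) and raw (boundary rules)
# detection signals for a whole session
detection_signals <- function(features, cutoff_hz, fs) {
  vel_raw <- cbind(features$vel_x, features$vel_y, features$vel_z)
  vel_raw[is.na(vel_raw)] <- 0
  speed <- features$speed
  speed[is.na(speed)] <- 0
  list(speed = lowpass_zero_phase(speed, cutoff_hz, fs),
       vel = apply(vel_raw, 2, lowpass_zero_phase, cutoff_hz, fs),
       vel_raw = vel_raw)
}

# candidate Reach Start / End times by the positive/negative-crossing and
# sub-5%-minimum rules on the reach-aligned velocity va; returns index or NA.
# "Positive"/"negative" are taken relative to a small velocity-resolution
# guard `z` (zero_frac of the peak, ~0.04 mm/s for a typical reach) rather
# than exactly 0: an exact-zero crossing is ill-conditioned when the hand is
# at rest, where residual tremor or numerical noise keeps the projected
# velocity wandering at negligible amplitude.
find_boundary <- function(va, peak_idx, v_ref, frac = 0.05, side,
                          zero_frac = 1e-4) {
  n <- length(va)
  thr <- frac * v_ref
  z <- zero_frac * v_ref
  if (side == "start") {
    rng <- seq_len(peak_idx - 1)
    if (length(rng) < 2) return(NA_integer_)
    cross <- which(va[rng][-length(rng)] <= z & va[rng][-1] > z) + 1L
    i <- 2:(peak_idx - 1)
    mins <- i[va[i] < va[i - 1] & va[i] <= va[i + 1] & va[i] < thr]
    cand <- c(cross, mins)
    if (!length(cand)) return(NA_integer_)
    max(cand)
  } else {
    if (peak_idx >= n - 1) return(NA_integer_)
    rng <- peak_idx:n
    cross <- which(va[rng][-length(rng)] > z & va[rng][-1] <= z) +
      peak_idx - 1L
    i <- (peak_idx + 1):(n - 1)
    mins <- i[va[i] <= va[i - 1] & va[i] < va[i + 1] & va[i] < thr]
    cand <- c(cross, mins)
    if (!length(cand)) return(NA_integer_)
    min(cand)
  }
}

#' Detect one reach from kinematic features
#'
#' Fingertip speed is zero-phase low-pass filtered at `cutoff_hz` and the
#' peak speed located in a window from 0.5 s before to 2.5 s after the target
#' display time; the dominant reach direction is the mean low-pass-filtered
#' 3D velocity in a 0.5 s window around the peak. The boundary rules then run
#' on the unfiltered velocity from 2 s before to 2 s after the peak,
#' projected onto that direction: Reach Start is the last time before the
#' peak at which the reach-aligned velocity became positive or displayed a
#' minimum below 5% of the peak reach-aligned velocity; Reach End is the
#' first such event (negative crossing or sub-5% minimum) after the peak.
#' (The low-pass filter protects peak picking from tremor; the boundary rules
#' use the unfiltered projection because a zero-phase filter spreads movement
#' energy across the true onset, biasing the crossings early - residual
#' tremor and drift at the boundaries are what the sub-5%-minimum rule is
#' for.)
#'
#' @param features kinematic feature frame from [compute_features()];
#'   detection is most accurate on minimally smoothed features
#'   (`kernel_sd_ms = 0`, interpolation only).
#' @param t_target_on target display (go) time, s.
#' @param cutoff_hz low-pass cutoff for detection (default 3 Hz).
#' @param peak_window window around `t_target_on` searched for peak speed,
#'   s (default c(-0.5, 2.5)).
#' @param min_frac sub-minimum threshold as a fraction of peak reach-aligned
#'   velocity (default 0.05).
#' @param filtered optional list(speed, vel, vel_raw) of precomputed signals
#'   for the whole session (computed on the fly when NULL).
#' @return one-row data.frame: t_go, t_peak, t_start, t_end, duration, valid,
#'   reason.
#' @export
detect_reach <- function(features, t_target_on, cutoff_hz = 3,
                         peak_window = c(-0.5, 2.5), min_frac = 0.05,
                         filtered = NULL) {
  t <- features$t
  fs <- 1 / stats::median(diff(t))
  if (is.null(filtered)) filtered <- detection_signals(features, cutoff_hz, fs)
  invalid <- function(reason) data.frame(
    t_go = t_target_on, t_peak = NA_real_, t_start = NA_real_,
    t_end = NA_real_, duration = NA_real_, valid = FALSE, reason = reason)

  win <- which(t >= t_target_on + peak_window[1] &
                 t <= t_target_on + peak_window[2])
  if (length(win) < 3) return(invalid("undetectable"))
  sp <- filtered$speed
  pk_rel <- which.max(sp[win])
  pk <- win[pk_rel]
  # a qualifying peak must be a local maximum interior to the search window
  if (pk_rel == 1 || pk_rel == length(win) ||
      sp[pk] <= sp[pk - 1] || sp[pk] < sp[pk + 1]) {
    return(invalid("undetectable"))
  }

  dwin <- which(t >= t[pk] - 0.25 & t <= t[pk] + 0.25)
  u <- colMeans(filtered$vel[dwin, , drop = FALSE])
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(invalid("undetectable"))
  u <- u / nu

  pwin <- which(t >= t[pk] - 2 & t <= t[pk] + 2)
  va <- as.numeric(filtered$vel_raw[pwin, , drop = FALSE] %*% u)
  pk_i <- match(pk, pwin)
  v_ref <- va[pk_i]
  if (!is.finite(v_ref) || v_ref <= 0) return(invalid("undetectable"))

  i_start <- find_boundary(va, pk_i, v_ref, min_frac, "start")
  i_end <- find_boundary(va, pk_i, v_ref, min_frac, "end")
  if (is.na(i_start) || is.na(i_end)) return(invalid("undetectable"))
  t_start <- t[pwin[i_start]]
  t_end <- t[pwin[i_end]]
  data.frame(t_go = t_target_on, t_peak = t[pk], t_start = t_start,
             t_end = t_end, duration = t_end - t_start, valid = TRUE,
             reason = "")
}

#' Detect all reaches of a session
#'
#' Derives one outward go event per trial (outer-target onset) and one inward
#' go event (outer-target offset / center re-display) from the event table,
#' and runs [detect_reach()] on each. Direction labels group each outward
#' reach with the inward reach from the diametrically opposite target, so
#' that reaches moving the hand in the same direction share a label.
#'
#' @param features 50 ms-smoothed kinematic feature frame.
#' @param events event table (columns trial, target_id, target_on_s).
#' @param config the [task_config()] (for target count and display duration).
#' @inheritParams detect_reach
#' @return data.frame of reach events with columns trial, target_id, outward,
#'   direction_label, t_go, t_peak, t_start, t_end, duration, valid, reason.
#' @export
detect_reaches <- function(features, events, config, cutoff_hz = 3,
                           peak_window = c(-0.5, 2.5), min_frac = 0.05) {
  t <- features$t
  fs <- 1 / stats::median(diff(t))
  filtered <- detection_signals(features, cutoff_hz, fs)
  nt <- config$n_targets
  opposite <- function(k) ((k - 1L + nt %/% 2L) %% nt) + 1L
  rows <- vector("list", 2L * nrow(events))
  for (i in seq_len(nrow(events))) {
    tid <- events$target_id[i]
    out <- detect_reach(features, events$target_on_s[i], cutoff_hz,
                        peak_window, min_frac, filtered)
    inw <- detect_reach(features,
                        events$target_on_s[i] + config$target_display_s,
                        cutoff_hz, peak_window, min_frac, filtered)
    rows[[2 * i - 1]] <- cbind(
      data.frame(trial = events$trial[i], target_id = tid, outward = TRUE,
                 direction_label = tid), out)
    rows[[2 * i]] <- cbind(
      data.frame(trial = events$trial[i], target_id = tid, outward = FALSE,
                 direction_label = opposite(tid)), inw)
  }
  do.call(rbind, rows)
}

#' Curate detected reaches
#'
#' Excludes duration outliers (duration above Q3 + `iqr_mult` * IQR of the
#' valid reach durations, quartiles by linear interpolation between order
#' statistics) and flags the session for exclusion when fewer than
#' `min_valid` valid reaches remain.
#'
#' @param reaches reach table from [detect_reaches()].
#' @param min_valid minimum number of valid reaches for a usable session
#'   (default 25).
#' @param iqr_mult IQR multiplier for the outlier threshold (default 1.5).
#' @return the reach table with updated valid/reason columns and attributes
#'   `duration_threshold` and `session_excluded`.
#' @export
curate_reaches <- function(reaches, min_valid = 25L, iqr_mult = 1.5) {
  if (is.null(reaches) || nrow(reaches) == 0) stop("empty reach table")
  d <- reaches$duration[reaches$valid]
  thr <- Inf
  if (length(d) >= 2) {
    q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
    thr <- q[2] + iqr_mult * (q[2] - q[1])
    out <- reaches$valid & reaches$duration > thr
    reaches$valid[out] <- FALSE
    reaches$reason[out] <- "duration_outlier"
  }
  attr(reaches, "duration_threshold") <- thr
  attr(reaches, "session_excluded") <- sum(reaches$valid) < min_valid
  reaches
}
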