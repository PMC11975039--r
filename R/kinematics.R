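#' Interpolate dropped frames and smooth a trajectory
#'
#' Invalid samples are replaced by linear interpolation between the nearest
#' valid neighbors; leading/trailing invalid runs are never extrapolated and
#' stay flagged invalid. Each coordinate is then convolved with a normalized
#' Gaussian kernel (truncated at +/- 4 sd). Samples within one kernel
#' half-width of a refused-extrapolation region are masked invalid.
#'
#' @param traj a `trajectory_series` (see [generate_trajectory()]).
#' @param kernel_sd_ms Gaussian kernel sd in ms; 50 for peri-reach modulation
#'   analyses, 15 for regression analyses.
#' @return a smoothed `trajectory_series` on the same time grid.
#' @export
interpolate_and_smooth <- function(traj, kernel_sd_ms = 50) {
  t <- traj$t
  n <- length(t)
  valid <- traj$valid & !is.na(traj$pos[, 1])
  if (sum(valid) < 2) stop("need at least 2 valid samples")
  vidx <- which(valid)
  lead_na <- seq_len(vidx[1] - 1)
  trail_na <- if (vidx[length(vidx)] < n) (vidx[length(vidx)] + 1):n
              else integer(0)
  interior <- vidx[1]:vidx[length(vidx)]

  pos <- traj$pos
  for (j in 1:3) {
    pos[interior, j] <- stats::approx(t[vidx], traj$pos[vidx, j],
                                      xout = t[interior])$y
  }

  sd_samples <- kernel_sd_ms / 1000 * traj$fps
  k <- gaussian_kernel(sd_samples)
  half <- (length(k) - 1) %/% 2
  sm <- pos
  for (j in 1:3) {
    x <- pos[, j]
    x[c(lead_na, trail_na)] <- NA
    sm[, j] <- convolve_renorm(x, k)
  }

  out_valid <- rep(TRUE, n)
  bad <- c(lead_na, trail_na)
  if (length(bad)) {
    near <- unique(pmin(pmax(rep(bad, each = 2 * half + 1) +
                               rep(-half:half, length(bad)), 1L), n))
    out_valid[near] <- FALSE
    sm[bad, ] <- NA_real_
  }
  structure(list(t = t, pos = sm, valid = out_valid, fps = traj$fps),
            ground_truth = attr(traj, "ground_truth"),
            class = "trajectory_series")
}

#' Differentiate a smoothed trajectory into kinematic features
#'
#' Velocity is obtained by central differences on the native frame grid
#' (one-sided at the edges); acceleration by applying the same operator to
#' velocity. Speed and acceleration magnitude are vector norms; signed
#' acceleration is the acceleration magnitude signed by whether the hand is
#' speeding up or braking (see [signed_acceleration()]).
#'
#' @param traj a smoothed `trajectory_series`.
#' @return data.frame of per-frame kinematic features: t, valid, pos_*, vel_*,
#'   speed, acc_*, acc_mag, acc_signed.
#' @export
differentiate <- function(traj) {
  t <- traj$t
  n <- length(t)
  if (n < 3) stop("need at least 3 samples to differentiate")
  p <- traj$pos
  d1 <- function(x) {
    v <- numeric(n)
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    v[1] <- (x[2] - x[1]) / (t[2] - t[1])
    v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
    v
  }
  v <- apply(p, 2, d1)
  a <- apply(v, 2, d1)
  speed <- sqrt(rowSums(v^2))
  a_mag <- sqrt(rowSums(a^2))
  a_signed <- signed_acceleration(v, a)
  data.frame(
    t = t, valid = traj$valid,
    pos_x = p[, 1], pos_y = p[, 2], pos_z = p[, 3],
    vel_x = v[, 1], vel_y = v[, 2], vel_z = v[, 3],
    speed = speed,
    acc_x = a[, 1], acc_y = a[, 2], acc_z = a[, 3],
    acc_mag = a_mag, acc_signed = a_signed
  )
}

#' Signed acceleration
#'
#' Acceleration magnitude signed by the dot product of velocity and
#' acceleration: positive while the hand speeds up along its path, negative
#' while it brakes, zero when v . a = 0. (This is the only scalar sign of the
#' velocity/acceleration pair that distinguishes acceleration from braking:
#' sign(v . a) = sign(d|v|/dt) wherever v != 0.)
#'
#' @param v n x 3 velocity matrix (or 3-vector).
#' @param a n x 3 acceleration matrix (or 3-vector).
#' @return numeric vector of signed accelerations, mm/s^2.
#' @export
signed_acceleration <- function(v, a) {
  if (is.null(dim(v))) v <- matrix(v, 1)
  if (is.null(dim(a))) a <- matrix(a, 1)
  sqrt(rowSums(a^2)) * sign(rowSums(v * a))
}

#' Full kinematic feature extraction
#'
#' Convenience wrapper: interpolate dropped frames, smooth with the requested
#' kernel, and differentiate.
#'
#' @inheritParams interpolate_and_smooth
#' @return data.frame of kinematic features (see [differentiate()]).
#' @export
compute_features <- function(traj, kernel_sd_ms = 50) {
  differentiate(interpolate_and_smooth(traj, kernel_sd_ms))
}
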