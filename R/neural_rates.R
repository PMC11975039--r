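#' Fractional-interval firing rate on a 1 ms grid
#'
#' Within each inter-spike interval of length L the instantaneous rate is
#' 1/L; each 1 ms bin carries the time-average of that rate over the bin, so
#' bins wholly inside an interval carry exactly 1/L and bins straddling a
#' spike carry the duration-weighted mixture of the two adjacent intervals'
#' rates. Bins before the first spike / after the last spike carry the first /
#' last interval's rate. This construction conserves the integral: each
#' inter-spike interval contributes exactly 1 to the integral of the rate.
#'
#' @param spike_times sorted spike times, s.
#' @param span numeric length-2 session span `c(t0, t1)`, s.
#' @param unit_id identifier stored with the result.
#' @param bin_s bin width, s (default 0.001).
#' @return object of class `rate_function`: list(unit_id, t0, dt, rate,
#'   kernel_sd_ms = 0, normalized = FALSE, degenerate).
#' @export
fractional_interval_rate <- function(spike_times, span, unit_id = NA,
                                     bin_s = 0.001) {
  stopifnot(length(span) == 2, span[2] > span[1])
  edges <- seq(span[1], span[2], by = bin_s)
  n <- length(edges) - 1L
  s <- unique(sort(spike_times)) # coincident spikes carry no ISI information
  if (length(s) < 2) {
    warning("fewer than 2 spikes; rate defined as 0")
    return(structure(list(unit_id = unit_id, t0 = span[1], dt = bin_s,
                          rate = rep(0, n), kernel_sd_ms = 0,
                          normalized = FALSE, degenerate = TRUE),
                     class = "rate_function"))
  }
  # cumulative spike-count function: linear through (s_i, i - 1), extended
  # with the edge intervals' slopes; bin rate = increment / bin width
  ns <- length(s)
  cs <- cum_spike_fun(edges, s)
  rate <- diff(cs) / bin_s
  structure(list(unit_id = unit_id, t0 = span[1], dt = bin_s, rate = rate,
                 kernel_sd_ms = 0, normalized = FALSE, degenerate = FALSE),
            class = "rate_function")
}

# piecewise-linear cumulative spike function evaluated at x, extrapolated
# with the first/last inter-spike interval's slope
cum_spike_fun <- function(x, s) {
  ns <- length(s)
  y <- stats::approx(s, seq_len(ns) - 1, xout = x, rule = 2)$y
  lo <- x < s[1]
  hi <- x > s[ns]
  if (any(lo)) y[lo] <- (x[lo] - s[1]) / (s[2] - s[1])
  if (any(hi)) y[hi] <- (ns - 1) + (x[hi] - s[ns]) / (s[ns] - s[ns - 1])
  y
}

#' Smooth a rate function with a Gaussian kernel
#'
#' Normalized Gaussian convolution on the 1 ms grid (truncated at +/- 4 sd,
#' renormalized to unit sum, edge-renormalized so constants are preserved).
#'
#' @param rate_fn a `rate_function`.
#' @param kernel_sd_ms kernel sd in ms; 50 for peri-reach modulation
#'   analyses, 15 for regression analyses.
#' @return a smoothed `rate_function`.
#' @export
smooth_rate <- function(rate_fn, kernel_sd_ms = 50) {
  sd_samples <- kernel_sd_ms / 1000 / rate_fn$dt
  k <- gaussian_kernel(sd_samples)
  rate_fn$rate <- convolve_renorm(rate_fn$rate, k)
  rate_fn$kernel_sd_ms <- kernel_sd_ms
  rate_fn
}

#' Sliding-window z-score normalization of a rate function
#'
#' At each bin the mean and sd are computed over a centered window (truncated
#' at the session edges) and the rate is z-scored against them, countering
#' slow drifts in spike amplitude / excitability. Windows with sd below
#' `sd_floor` yield 0 and are flagged.
#'
#' @param rate_fn a `rate_function`.
#' @param window_s sliding window length, s (default 45).
#' @param sd_floor minimum sd, spikes/s (default 1e-6).
#' @return a z-scored `rate_function` (field `normalized = TRUE`, logical
#'   field `flat` marking zero-variance bins).
#' @export
sliding_zscore <- function(rate_fn, window_s = 45, sd_floor = 1e-6) {
  x <- rate_fn$rate
  n <- length(x)
  half <- max(1L, round(window_s / rate_fn$dt / 2))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  m <- hi - lo + 1
  s1 <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  mu <- s1 / m
  varw <- pmax((s2 - s1^2 / m) / pmax(m - 1, 1), 0)
  sdw <- sqrt(varw)
  flat <- sdw < sd_floor
  z <- ifelse(flat, 0, (x - mu) / sdw)
  rate_fn$rate <- z
  rate_fn$normalized <- TRUE
  rate_fn$flat <- flat
  rate_fn
}

#' Evaluate a rate function at arbitrary times
#'
#' Linear interpolation between bin centers; evaluation at bin centers
#' reproduces the stored values exactly. Times outside the span clamp to the
#' nearest bin.
#'
#' @param rate_fn a `rate_function`.
#' @param times numeric vector of times, s.
#' @return numeric vector of rates.
#' @export
eval_rate <- function(rate_fn, times) {
  centers_t0 <- rate_fn$t0 + rate_fn$dt / 2
  idx <- (times - centers_t0) / rate_fn$dt
  n <- length(rate_fn$rate)
  # snap to the grid within a nanosecond-scale tolerance so evaluation at bin
  # centers reproduces stored values exactly
  snap <- abs(idx - round(idx)) < 1e-6
  idx[snap] <- round(idx[snap])
  i0 <- floor(idx)
  frac <- idx - i0
  i1 <- pmin(pmax(i0 + 1L, 1L), n)
  i2 <- pmin(pmax(i0 + 2L, 1L), n)
  rate_fn$rate[i1] * (1 - frac) + rate_fn$rate[i2] * frac
}

#' Nearest-bin indices of times in a rate function
#'
#' Used by the lagged-regression and circular-shift machinery, which shifts
#' firing-rate sample indices rather than re-interpolating.
#'
#' @param rate_fn a `rate_function`.
#' @param times numeric vector of times, s.
#' @return integer bin indices in 1..length(rate).
#' @export
rate_bin_index <- function(rate_fn, times) {
  i <- as.integer(floor((times - rate_fn$t0) / rate_fn$dt)) + 1L
  pmin(pmax(i, 1L), length(rate_fn$rate))
}
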