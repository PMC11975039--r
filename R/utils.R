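#' Derive a child seed from a master seed
#'
#' All Monte-Carlo stages draw their randomness from streams derived from a
#' single master seed, so that e.g. adding a unit to a simulated session does
#' not perturb the spike trains of the other units.
#'
#' @param master integer master seed.
#' @param stream integer stream identifier (>= 0).
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(master, stream) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(stream) * 16807 + 1
  as.integer(s %% (m - 1) + 1)
}

#' Truncated, renormalized Gaussian kernel
#'
#' @param sd_samples kernel standard deviation in samples.
#' @return numeric kernel of odd length, summing to 1, truncated at +/- 4 sd.
#' @keywords internal
gaussian_kernel <- function(sd_samples) {
  if (sd_samples <= 0) return(1)
  half <- max(1L, ceiling(4 * sd_samples))
  x <- (-half):half
  k <- exp(-0.5 * (x / sd_samples)^2)
  k / sum(k)
}

#' Normalized convolution with edge correction
#'
#' Convolves `x` with `kernel` (unit sum); near the edges the result is
#' renormalized by the in-range kernel mass so constants are preserved
#' everywhere. NA entries in `x` contribute zero weight.
#'
#' @keywords internal
convolve_renorm <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  if (m == 1) return(x * kernel)
  half <- (m - 1) %/% 2
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  num <- conv_open(x0, kernel)[(half + 1):(half + n)]
  if (all(ok)) {
    # in-range kernel mass depends only on distance from the edges
    # (kernel is symmetric and sums to 1)
    den <- rep(1, n)
    sfx <- rev(cumsum(rev(kernel)))     # sfx[j] = sum(kernel[j:m])
    i <- seq_len(min(half, n))
    den[i] <- sfx[half + 2 - i]
    den[n + 1 - i] <- sfx[half + 2 - i]
  } else {
    den <- conv_open(as.numeric(ok), kernel)[(half + 1):(half + n)]
  }
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  out[!ok] <- NA_real_
  out
}

# full linear convolution via FFT, zero-padded to a highly composite length
conv_open <- function(x, k) {
  n <- length(x)
  m <- length(k)
  L <- stats::nextn(n + m - 1, c(2, 3, 5))
  xf <- stats::fft(c(x, numeric(L - n)))
  kf <- stats::fft(c(k, numeric(L - m)))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n + m - 1)] / L
}

#' Runs of TRUE values in a logical vector
#'
#' @return data.frame with columns start, end, length (empty if none).
#' @keywords internal
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
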