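#' Regressor column-to-group map
#'
#' The "kinematics_only" set has 12 columns in 6 groups (3D position, 3D
#' velocity, speed, 3D acceleration, acceleration magnitude, signed
#' acceleration); "kinematics_plus_error" adds 3D error and error magnitude
#' (16 columns, 8 groups).
#'
#' @param set "kinematics_only" or "kinematics_plus_error".
#' @return named character vector mapping column name to group name.
#' @export
regressor_groups <- function(set = c("kinematics_plus_error",
                                     "kinematics_only")) {
  set <- match.arg(set)
  g <- c(pos_x = "pos3d", pos_y = "pos3d", pos_z = "pos3d",
         vel_x = "vel3d", vel_y = "vel3d", vel_z = "vel3d",
         speed = "speed",
         acc_x = "acc3d", acc_y = "acc3d", acc_z = "acc3d",
         acc_mag = "acc_mag", acc_signed = "acc_signed")
  if (set == "kinematics_plus_error") {
    g <- c(g, err_x = "err3d", err_y = "err3d", err_z = "err3d",
           err_mag = "err_mag")
  }
  g
}

#' Build the regression design from kinematic features and curated reaches
#'
#' Concatenates per-reach samples at the native kinematic sample times. For
#' the default `reach_window`, samples run from 250 ms before each valid
#' Reach Start to 250 ms after its Reach End; the windowed variants take
#' 500 ms wide windows centered on Reach Start or Reach End. The 3D error
#' columns are the instantaneous position minus that reach's goal position,
#' estimated as the mean position 0-1 s after Reach End (the early hold over
#' the target, which averages out tremor); reaches whose hold window extends
#' past the recording are dropped from the error-model samples with a
#' warning.
#'
#' @param features 15 ms-smoothed kinematic feature frame.
#' @param reaches curated reach table.
#' @param window "reach_window", "start_centered_500ms" or
#'   "end_centered_500ms".
#' @param pad_s reach-window padding, s (default 0.25).
#' @return object of class `encoding_design`: list(t, reach, X) where X has
#'   the 16 regressor columns (err_* rows NA for reaches without a usable
#'   hold window).
#' @export
build_design <- function(features, reaches, window = "reach_window",
                         pad_s = 0.25) {
  window <- match.arg(window, c("reach_window", "start_centered_500ms",
                                "end_centered_500ms"))
  rr <- reaches[reaches$valid, , drop = FALSE]
  if (nrow(rr) == 0) stop("no valid reaches")
  t <- features$t
  t_max <- max(t)
  cols <- c("pos_x", "pos_y", "pos_z", "vel_x", "vel_y", "vel_z", "speed",
            "acc_x", "acc_y", "acc_z", "acc_mag", "acc_signed")
  pieces <- vector("list", nrow(rr))
  n_dropped_err <- 0L
  for (i in seq_len(nrow(rr))) {
    rng <- switch(window,
      reach_window = c(rr$t_start[i] - pad_s, rr$t_end[i] + pad_s),
      start_centered_500ms = rr$t_start[i] + c(-0.25, 0.25),
      end_centered_500ms = rr$t_end[i] + c(-0.25, 0.25))
    idx <- which(t >= rng[1] & t <= rng[2] & features$valid)
    if (!length(idx)) next
    X <- as.matrix(features[idx, cols])
    hold <- which(t > rr$t_end[i] & t <= rr$t_end[i] + 1 & features$valid)
    if (rr$t_end[i] + 1 > t_max || length(hold) < 2) {
      n_dropped_err <- n_dropped_err + 1L
      err <- matrix(NA_real_, length(idx), 3)
    } else {
      goal <- c(mean(features$pos_x[hold]), mean(features$pos_y[hold]),
                mean(features$pos_z[hold]))
      err <- cbind(features$pos_x[idx] - goal[1],
                   features$pos_y[idx] - goal[2],
                   features$pos_z[idx] - goal[3])
    }
    X <- cbind(X, err_x = err[, 1], err_y = err[, 2], err_z = err[, 3],
               err_mag = sqrt(rowSums(err^2)))
    pieces[[i]] <- list(t = t[idx], reach = rep(i, length(idx)), X = X)
  }
  if (n_dropped_err > 0) {
    warning(sprintf(
      "%d reach(es) without a full 1 s hold window dropped from error-model samples",
      n_dropped_err))
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  structure(list(
    t = unlist(lapply(pieces, `[[`, "t")),
    reach = unlist(lapply(pieces, `[[`, "reach")),
    X = do.call(rbind, lapply(pieces, `[[`, "X")),
    window = window
  ), class = "encoding_design")
}

# center/scale columns to mean 0 sd 1, dropping zero-variance columns;
# returns list(X, dropped)
normalize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  Xn <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  list(X = Xn, dropped = colnames(X)[!keep])
}

# select the set's columns and rows with complete data; normalized design +
# thin-QR Q for fast repeated R^2 evaluation
prepare_design <- function(design, set) {
  cols <- names(regressor_groups(set))
  X <- design$X[, cols, drop = FALSE]
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  nz <- normalize_columns(X)
  if (length(nz$dropped)) {
    warning("zero-variance column(s) dropped: ",
            paste(nz$dropped, collapse = ", "))
  }
  qr_x <- qr(nz$X)
  if (qr_x$rank < ncol(nz$X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("rank-deficient design; dropping ",
            ncol(nz$X) - qr_x$rank, " column(s)")
    nz$X <- nz$X[, sort(keep), drop = FALSE]
    qr_x <- qr(nz$X)
  }
  list(X = nz$X, Q = qr.Q(qr_x), t = design$t[ok], rows = which(ok),
       dropped = nz$dropped)
}

# FR sample matrix at a base index vector plus integer bin shifts, wrapping
# circularly at the recording edges; returns R^2 per shift against Q
r2_for_shifts <- function(Q, rate, idx0, shifts_bins, chunk = 500L) {
  n_bins <- length(rate)
  out <- numeric(length(shifts_bins))
  for (ch in split(seq_along(shifts_bins),
                   ceiling(seq_along(shifts_bins) / chunk))) {
    idx <- outer(idx0 - 1L, shifts_bins[ch], `+`) %% n_bins + 1L
    Y <- matrix(rate[idx], nrow = length(idx0))
    Yc <- sweep(Y, 2, colMeans(Y))
    cp <- crossprod(Q, Yc)
    ss <- colSums(Yc^2)
    out[ch] <- ifelse(ss > 0, colSums(cp^2) / ss, 0)
  }
  out
}

#' Lagged multiple linear regression of firing rate on kinematic features
#'
#' Regresses the unit's (15 ms-smoothed, drift-normalized) firing rate,
#' evaluated at the design sample times offset by each lag, on the normalized
#' regressor columns. Positive lags mean the neural data follow the
#' kinematics. Both the response and the regressors are centered and scaled;
#' R-squared and Ezekiel-adjusted R-squared are recorded per lag, and the
#' optimal lag maximizes R-squared.
#'
#' @param design an `encoding_design` from [build_design()].
#' @param rate_fn a 15 ms-smoothed, sliding-z-scored `rate_function`.
#' @param set regressor set (see [regressor_groups()]).
#' @param lags_s numeric vector of lags in s (default -1 to +1 in 1/120 s
#'   steps, 241 lags).
#' @return object of class `lagged_fit`: list(set, lags_s, r2, adj_r2,
#'   opt_lag_s, opt_r2, opt_adj_r2, n, p, prep).
#' @export
lagged_regression <- function(design, rate_fn,
                              set = "kinematics_only",
                              lags_s = seq(-1, 1, by = 1 / 120)) {
  prep <- prepare_design(design, set)
  idx0 <- rate_bin_index(rate_fn, prep$t)
  shifts <- as.integer(round(lags_s / rate_fn$dt))
  r2 <- r2_for_shifts(prep$Q, rate_fn$rate, idx0, shifts)
  n <- nrow(prep$X)
  p <- ncol(prep$X)
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  best <- which.max(r2)
  structure(list(set = set, lags_s = lags_s, r2 = r2, adj_r2 = adj,
                 opt_lag_s = lags_s[best], opt_r2 = r2[best],
                 opt_adj_r2 = adj[best], n = n, p = p, prep = prep),
            class = "lagged_fit")
}

#' R-squared as a function of circular firing-rate shift, for every 1 ms bin
#'
#' Computes the regression R-squared obtained when the firing-rate evaluation
#' indices are circularly shifted by s bins, for all N possible shifts at
#' once, via FFT cross-correlations of the rate (and its square) with the
#' design's orthonormalized columns scattered onto the rate grid. Because the
#' normalized design is centered, the projection of the shifted, centered
#' response onto the design column space reduces to plain cross-correlation
#' sums, so the entire curve costs p + 2 FFTs.
#'
#' @param prep prepared design (internal, from a `lagged_fit`).
#' @param rate_fn the `rate_function` used for the fit.
#' @return numeric vector r2 of length N (bins); r2[s + 1] is the R-squared
#'   at shift s.
#' @keywords internal
r2_shift_curve <- function(prep, rate_fn) {
  rate <- rate_fn$rate
  N <- length(rate)
  n <- nrow(prep$Q)
  idx0 <- rate_bin_index(rate_fn, prep$t)

  scatter <- function(vals) {
    out <- numeric(N)
    sums <- rowsum(vals, idx0)
    out[as.integer(rownames(sums))] <- sums
    out
  }
  # circular cross-correlation c(s) = sum_b w[b] * rate[b + s] via linear
  # FFT correlation on a padded grid, folding the wrap-around part back
  L <- stats::nextn(2L * N - 1L, c(2, 3, 5))
  R1 <- stats::fft(c(rate, numeric(L - N)))
  R2f <- stats::fft(c(rate^2, numeric(L - N)))
  xcorr <- function(w, Rf) {
    lin <- Re(stats::fft(Conj(stats::fft(c(w, numeric(L - N)))) * Rf,
                         inverse = TRUE)) / L
    # lin[j + 1] holds linear-correlation lag j, with negative lags wrapped
    # to index L + j + 1; the circular correlation at shift s in 0..N-1 is
    # lag s plus lag s - N (index L + s - N + 1)
    lin[1:N] + lin[(L - N + 1):L]
  }
  num <- 0
  for (j in seq_len(ncol(prep$Q))) {
    num <- num + xcorr(scatter(prep$Q[, j]), R1)^2
  }
  cnt <- scatter(rep(1, n))
  m <- xcorr(cnt, R1)
  ss <- xcorr(cnt, R2f)
  den <- ss - m^2 / n
  ifelse(den > 1e-12, num / den, 0)
}

#' Circular-shift null distribution for regression significance
#'
#' Builds the chance R-squared distribution by shifting the firing-rate
#' evaluation indices circularly by offsets drawn uniformly over the whole
#' recording (wrap-around at the edges preserves the rate's autocorrelation
#' while destroying its alignment with the kinematics). With the default
#' `statistic = "max_lag"`, every null draw undergoes the same optimal-lag
#' search as the observed statistic (the maximum R-squared over the lag grid
#' around the random offset), so the null p-values are uniform under
#' independence despite the optimal-lag selection; `statistic = "fixed_lag"`
#' instead refits each offset at the observed optimal lag only. The unit is
#' significant when the observed statistic exceeds the 99th percentile of
#' the null (`alpha` = 0.01, one-sided).
#'
#' @param fit a `lagged_fit` from [lagged_regression()].
#' @param rate_fn the same `rate_function` used for the fit.
#' @param n_shifts number of random shifts (default 10000).
#' @param seed integer seed.
#' @param alpha one-sided significance level (default 0.01).
#' @param statistic "max_lag" (selection-consistent, default) or "fixed_lag".
#' @return list(null_r2, p, crit, significant, observed).
#' @export
circular_shift_null <- function(fit, rate_fn, n_shifts = 10000L, seed = 1L,
                                alpha = 0.01,
                                statistic = c("max_lag", "fixed_lag")) {
  statistic <- match.arg(statistic)
  set.seed(derive_seed(seed, 11L))
  n_bins <- length(rate_fn$rate)
  offsets <- sample.int(n_bins, n_shifts, replace = TRUE) - 1L
  if (statistic == "max_lag") {
    curve <- r2_shift_curve(fit$prep, rate_fn)
    lag_bins <- as.integer(round(fit$lags_s / rate_fn$dt))
    grid_at <- function(s) max(curve[(s + lag_bins) %% n_bins + 1L])
    observed <- grid_at(0L)
    null_r2 <- vapply(offsets, grid_at, numeric(1))
  } else {
    base_shift <- as.integer(round(fit$opt_lag_s / rate_fn$dt))
    idx0 <- rate_bin_index(rate_fn, fit$prep$t)
    observed <- fit$opt_r2
    null_r2 <- r2_for_shifts(fit$prep$Q, rate_fn$rate, idx0,
                             base_shift + offsets)
  }
  crit <- stats::quantile(null_r2, 1 - alpha, names = FALSE)
  p <- (1 + sum(null_r2 >= observed)) / (n_shifts + 1)
  list(null_r2 = null_r2, p = p, crit = crit,
       significant = observed > crit, observed = observed)
}

#' Exact Shapley decomposition of regression R-squared
#'
#' Attributes the full-model R-squared to individual regressors as the
#' weighted average, with the standard weights |S|! (p - |S| - 1)! / p!, of
#' each regressor's marginal R-squared contribution over all 2^p regressor
#' subsets. Subset R-squared values are computed from the correlation (Gram)
#' matrix of the normalized design rather than by refitting on raw samples.
#' The per-column values sum exactly to the full-model R-squared
#' (efficiency); 3D feature groups are obtained by summing their component
#' columns.
#'
#' @param X design matrix (columns are regressors; centered/scaled
#'   internally, zero-variance columns dropped).
#' @param y response vector (centered/scaled internally).
#' @param groups named character vector mapping column names to group names
#'   (default from column names via [regressor_groups()] conventions; columns
#'   without a group map to themselves).
#' @param max_p maximum number of columns for exact enumeration (default 20).
#' @return list(values [per column], group_values, proportions,
#'   group_proportions, full_r2).
#' @export
shapley_decompose <- function(X, y, groups = NULL, max_p = 20L) {
  nz <- normalize_columns(as.matrix(X))
  if (length(nz$dropped)) {
    warning("zero-variance column(s) dropped: ",
            paste(nz$dropped, collapse = ", "))
  }
  Xn <- nz$X
  p <- ncol(Xn)
  if (p < 1) stop("no usable regressor columns")
  if (p > max_p) stop("exact Shapley enumeration limited to ", max_p,
                      " columns")
  yc <- as.numeric(scale(y))
  n <- length(yc)
  C <- crossprod(Xn) / (n - 1)
  b <- as.numeric(crossprod(Xn, yc)) / (n - 1)

  # subset R^2 = b_S' C_SS^{-1} b_S; fall back to the pseudo-inverse when a
  # subset is collinear (duplicated regressors), matching the limit of an
  # OLS refit on the subset
  sub_r2 <- function(S) {
    bS <- b[S]
    CS <- C[S, S, drop = FALSE]
    x <- tryCatch(solve(CS, bS), error = function(e) {
      sv <- svd(CS)
      pos <- sv$d > max(sv$d) * 1e-10
      sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], bS)) / sv$d[pos])
    })
    sum(bS * x)
  }
  n_sub <- bitwShiftL(1L, p)
  r2 <- numeric(n_sub)
  bits <- bitwShiftL(1L, 0:(p - 1))
  for (m in seq_len(n_sub - 1)) {
    r2[m + 1] <- sub_r2(which(bitwAnd(m, bits) > 0L))
  }

  masks <- 0:(n_sub - 1)
  popcnt <- rowSums(outer(masks, bits, function(a, b) bitwAnd(a, b) > 0L))
  wts <- exp(lfactorial(0:(p - 1)) + lfactorial(p - (0:(p - 1)) - 1) -
               lfactorial(p))
  values <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bits[i]
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- popcnt[without + 1]
    values[i] <- sum(wts[s + 1] * (r2[without + bit + 1] - r2[without + 1]))
  }
  names(values) <- colnames(Xn)
  full <- r2[n_sub]

  if (is.null(groups)) {
    gset <- regressor_groups("kinematics_plus_error")
    groups <- ifelse(colnames(Xn) %in% names(gset),
                     gset[colnames(Xn)], colnames(Xn))
    names(groups) <- colnames(Xn)
  }
  gv <- tapply(values, groups[names(values)], sum)
  list(values = values,
       group_values = gv[unique(groups[names(values)])],
       proportions = if (full > 0) values / full else values * 0,
       group_proportions = if (full > 0) gv / full else gv * 0,
       full_r2 = full)
}

#' Full encoding analysis for one unit
#'
#' Runs the lagged regression, the circular-shift significance test and the
#' Shapley decomposition at the optimal lag, for one regressor set.
#'
#' @inheritParams lagged_regression
#' @inheritParams circular_shift_null
#' @return object of class `encoding_result`: list(set, fit, null, shapley).
#' @export
encode_unit <- function(design, rate_fn, set = "kinematics_only",
                        lags_s = seq(-1, 1, by = 1 / 120),
                        n_shifts = 10000L, seed = 1L, alpha = 0.01,
                        statistic = "max_lag") {
  fit <- lagged_regression(design, rate_fn, set, lags_s)
  null <- circular_shift_null(fit, rate_fn, n_shifts, seed, alpha, statistic)
  shift <- as.integer(round(fit$opt_lag_s / rate_fn$dt))
  idx <- (rate_bin_index(rate_fn, fit$prep$t) - 1L + shift) %%
    length(rate_fn$rate) + 1L
  y <- rate_fn$rate[idx]
  shap <- shapley_decompose(fit$prep$X, y, groups = regressor_groups(set))
  structure(list(set = set, fit = fit, null = null, shapley = shap),
            class = "encoding_result")
}
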