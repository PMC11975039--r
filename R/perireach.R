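#' Build the peri-reach firing-rate grid
#'
#' For each valid reach the firing rate is sampled at 380 timepoints: 150
#' pre-reach samples at 10 ms steps covering [-1.5 s, Reach Start), 80 evenly
#' spaced in-reach samples (time-stretching: the same count regardless of
#' reach duration, so reaches align sample-to-sample), and 150 post-reach
#' samples over (Reach End, +1.5 s]. Alternative alignment modes sample at
#' fixed 10 ms steps around an anchor event instead of stretching.
#'
#' @param rate_fn a 50 ms-smoothed `rate_function`.
#' @param reaches curated reach table (only rows with `valid` are used).
#' @param mode one of "stretched", "realtime" (fixed steps from Reach Start),
#'   "go_aligned", "peak_aligned" (fixed steps centered on the anchor).
#' @param step_s pre/post sampling step, s (default 0.01).
#' @param in_reach_n number of in-reach samples (default 80).
#' @param endpoint_convention "inclusive" (samples include Reach Start and
#'   Reach End, spacing duration/79) or "midpoint" (bin midpoints, spacing
#'   duration/80).
#' @param features optional 50 ms kinematic feature frame; when supplied, the
#'   grand-mean speed profile is computed on the same grid by cubic-spline
#'   resampling.
#' @return object of class `peri_reach_grid`: list(fr [reaches x 380],
#'   phase, mask, grid_time, reaches, mode, speed_profile).
#' @export
build_grid <- function(rate_fn, reaches, mode = "stretched", step_s = 0.01,
                       in_reach_n = 80L, endpoint_convention = "inclusive",
                       features = NULL) {
  mode <- match.arg(mode, c("stretched", "realtime", "go_aligned",
                            "peak_aligned"))
  rr <- reaches[reaches$valid, , drop = FALSE]
  if (nrow(rr) == 0) stop("no valid reaches")
  min_dur <- 2 / 120
  short <- rr$duration < min_dur
  if (any(short)) {
    warning(sprintf("%d reach(es) shorter than 2 kinematic samples skipped",
                    sum(short)))
    rr <- rr[!short, , drop = FALSE]
  }
  n_pre <- round(1.5 / step_s)
  n_post <- n_pre
  n_cols <- n_pre + in_reach_n + n_post
  half <- in_reach_n %/% 2
  phase <- c(rep("pre", n_pre), rep("reach_first", half),
             rep("reach_second", in_reach_n - half), rep("post", n_post))
  mask_n <- round(0.4 / step_s)
  mask <- c(rep(FALSE, n_pre - mask_n), rep(TRUE, mask_n + in_reach_n +
                                              mask_n),
            rep(FALSE, n_post - mask_n))

  times <- matrix(NA_real_, nrow(rr), n_cols)
  if (mode == "stretched") {
    pre_off <- -1.5 + (seq_len(n_pre) - 1) * step_s
    post_off <- seq_len(n_post) * step_s
    for (i in seq_len(nrow(rr))) {
      inr <- if (endpoint_convention == "inclusive") {
        seq(rr$t_start[i], rr$t_end[i], length.out = in_reach_n)
      } else {
        rr$t_start[i] + (seq_len(in_reach_n) - 0.5) *
          rr$duration[i] / in_reach_n
      }
      times[i, ] <- c(rr$t_start[i] + pre_off, inr, rr$t_end[i] + post_off)
    }
  } else {
    anchor <- switch(mode,
                     realtime = rr$t_start,
                     go_aligned = rr$t_go,
                     peak_aligned = rr$t_peak)
    off <- (-(n_pre) + seq_len(n_cols) - 1) * step_s
    times <- outer(anchor, off, `+`)
  }
  fr <- matrix(eval_rate(rate_fn, as.numeric(times)), nrow(rr), n_cols)

  mean_dur <- mean(rr$duration)
  grid_time <- c(-1.5 + (seq_len(n_pre) - 1) * step_s,
                 seq(0, mean_dur, length.out = in_reach_n),
                 mean_dur + seq_len(n_post) * step_s)

  speed_profile <- NULL
  if (!is.null(features)) {
    sp_fun <- stats::splinefun(features$t, features$speed, method = "natural")
    sp <- matrix(sp_fun(as.numeric(times)), nrow(rr), n_cols)
    speed_profile <- colMeans(sp)
  }
  structure(list(fr = fr, phase = phase, mask = mask, grid_time = grid_time,
                 reaches = rr, mode = mode, step_s = step_s,
                 in_reach_n = in_reach_n, speed_profile = speed_profile),
            class = "peri_reach_grid")
}

#' Shuffle-derived baseline distribution of mean firing rates
#'
#' Each entry is the mean of `n_reaches` firing-rate values read at times
#' drawn uniformly at random from the entire recording (reach epochs
#' included), emulating the session-wide chance level for a mean across
#' reaches.
#'
#' @param rate_fn a `rate_function`.
#' @param n_reaches sample size per shuffle (the number of reaches).
#' @param n_shuffles number of shuffle draws (default 10000).
#' @param seed integer seed.
#' @return numeric vector of `n_shuffles` baseline mean rates.
#' @export
shuffle_baseline <- function(rate_fn, n_reaches, n_shuffles = 10000L,
                             seed = 1L) {
  set.seed(derive_seed(seed, 7L))
  n <- length(rate_fn$rate)
  idx <- sample.int(n, n_reaches * n_shuffles, replace = TRUE)
  colMeans(matrix(rate_fn$rate[idx], n_reaches, n_shuffles))
}

#' Test peri-reach firing-rate modulation against a shuffle baseline
#'
#' At each grid timepoint the observed mean peri-reach rate is compared
#' against the shuffle-derived baseline distribution; the empirical p-value
#' is the add-one-smoothed tail proportion, and the two-sided criterion at
#' level `alpha` is the union of the two alpha/2 tails (a sample is
#' significantly positive when the observed mean exceeds the 1 - alpha/2
#' baseline quantile, negative when below the alpha/2 quantile). Runs shorter
#' than `contiguity_min` samples are rejected, and the unit counts as
#' modulated only if a surviving run intersects the analysis window (400 ms
#' before Reach Start to 400 ms after Reach End).
#'
#' @param grid a `peri_reach_grid`.
#' @param baseline numeric vector from [shuffle_baseline()].
#' @param alpha two-sided significance level (default 0.01).
#' @param contiguity_min minimum run length in samples (default 5, i.e.
#'   about 50 ms).
#' @return object of class `modulation_result`: list(mean_fr, p_high, p_low,
#'   p, sign, intervals, is_modulated, degenerate).
#' @export
test_modulation <- function(grid, baseline, alpha = 0.01,
                            contiguity_min = 5L) {
  obs <- colMeans(grid$fr)
  nb <- length(baseline)
  sb <- sort(baseline)
  degenerate <- sb[nb] - sb[1] < 1e-9 * max(1, abs(sb[nb]))
  n_lt <- findInterval(obs, sb, left.open = TRUE)
  n_le <- findInterval(obs, sb)
  p_high <- (nb - n_lt + 1) / (nb + 1)
  p_low <- (n_le + 1) / (nb + 1)
  p <- pmin(1, 2 * pmin(p_high, p_low))
  sig_pos <- !degenerate & p_high < alpha / 2
  sig_neg <- !degenerate & p_low < alpha / 2
  sgn <- integer(length(obs))
  sgn[sig_pos] <- 1L
  sgn[sig_neg] <- -1L

  intervals <- lapply(c(1L, -1L), function(s) {
    r <- true_runs(sgn == s)
    r <- r[r$length >= contiguity_min, , drop = FALSE]
    if (nrow(r)) cbind(r, sign = s) else NULL
  })
  intervals <- do.call(rbind, intervals)
  if (is.null(intervals)) {
    intervals <- data.frame(start = integer(0), end = integer(0),
                            length = integer(0), sign = integer(0))
  }
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  if (nrow(intervals)) {
    intervals$onset_time <- grid$grid_time[intervals$start]
    intervals$end_time <- grid$grid_time[intervals$end]
    intervals$in_window <- vapply(seq_len(nrow(intervals)), function(i)
      any(grid$mask[intervals$start[i]:intervals$end[i]]), logical(1))
  } else {
    intervals$onset_time <- numeric(0)
    intervals$end_time <- numeric(0)
    intervals$in_window <- logical(0)
  }
  structure(list(mean_fr = obs, p_high = p_high, p_low = p_low, p = p,
                 sign = sgn, intervals = intervals,
                 is_modulated = any(intervals$in_window),
                 degenerate = degenerate),
            class = "modulation_result")
}

# tie-corrected Kruskal-Wallis p for one numeric vector and a prebuilt group
# factor (faster than kruskal.test in tight per-timepoint loops)
kw_pvalue <- function(x, g_idx, n_g, N, df) {
  r <- rank(x)
  Rg <- vapply(g_idx, function(ix) sum(r[ix]), numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / n_g) - 3 * (N + 1)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) return(1)
  stats::pchisq(H / C, df, lower.tail = FALSE)
}

#' Test directional tuning across reach-direction groups
#'
#' At each peri-reach timepoint the firing rates are compared across reach
#' directions with a tie-corrected Kruskal-Wallis ANOVA (outward reaches to a
#' target share a direction label with inward reaches from the opposite
#' target). A unit is significantly tuned when p < `alpha` holds for at least
#' `contiguity_min` contiguous samples with at least one run intersecting the
#' analysis window. Per-sample significance severity at p < 0.05 and p < 0.01
#' is retained.
#'
#' @param grid a `peri_reach_grid`.
#' @param labels direction label per grid reach (defaults to the grid's
#'   `direction_label` column).
#' @param alpha per-timepoint significance level (default 0.05).
#' @param contiguity_min minimum run length (default 5).
#' @param min_group_n minimum reaches per direction group (default 3); groups
#'   below it are dropped.
#' @return object of class `tuning_result`: list(p, severity, intervals,
#'   is_tuned, groups).
#' @export
test_directional_tuning <- function(grid, labels = NULL, alpha = 0.05,
                                    contiguity_min = 5L, min_group_n = 3L) {
  if (is.null(labels)) labels <- grid$reaches$direction_label
  stopifnot(length(labels) == nrow(grid$fr))
  g <- factor(labels)
  keep_lv <- names(which(table(g) >= min_group_n))
  keep <- g %in% keep_lv
  g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need >= 2 direction groups with enough reaches")
  fr <- grid$fr[keep, , drop = FALSE]
  g_idx <- split(seq_along(g), g)
  n_g <- lengths(g_idx)
  N <- length(g)
  df <- nlevels(g) - 1
  p <- vapply(seq_len(ncol(fr)), function(j)
    kw_pvalue(fr[, j], g_idx, n_g, N, df), numeric(1))
  severity <- ifelse(p < 0.01, "black", ifelse(p < 0.05, "gray", "ns"))

  r <- true_runs(p < alpha)
  r <- r[r$length >= contiguity_min, , drop = FALSE]
  if (nrow(r)) {
    r$onset_time <- grid$grid_time[r$start]
    r$end_time <- grid$grid_time[r$end]
    r$in_window <- vapply(seq_len(nrow(r)), function(i)
      any(grid$mask[r$start[i]:r$end[i]]), logical(1))
  } else {
    r$onset_time <- numeric(0); r$end_time <- numeric(0)
    r$in_window <- logical(0)
  }
  structure(list(p = p, severity = severity, intervals = r,
                 is_tuned = any(r$in_window), groups = levels(g)),
            class = "tuning_result")
}

#' Spatial activation heatmap in the top-2 principal-component plane
#'
#' Projects the 3D fingertip positions onto their top two principal
#' components, tiles that plane into `cell_mm` squares, and averages the
#' firing rate over all kinematic timepoints falling in each occupied cell.
#'
#' @param features kinematic feature frame (valid samples used).
#' @param rate_fn a `rate_function` evaluated at the kinematic sample times.
#' @param cell_mm grid cell edge length, mm (default 15).
#' @return data.frame(cell_x, cell_y, n, mean_fr) with attributes `rotation`,
#'   `center` and `var_explained` from the PCA.
#' @export
spatial_heatmap <- function(features, rate_fn, cell_mm = 15) {
  ok <- features$valid & is.finite(features$pos_x)
  X <- cbind(features$pos_x, features$pos_y, features$pos_z)[ok, ,
                                                             drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  fr <- eval_rate(rate_fn, features$t[ok])
  cx <- floor(sc[, 1] / cell_mm)
  cy <- floor(sc[, 2] / cell_mm)
  key <- paste(cx, cy)
  agg <- tapply(fr, key, mean)
  cnt <- tapply(fr, key, length)
  xy <- do.call(rbind, strsplit(names(agg), " "))
  out <- data.frame(cell_x = as.integer(xy[, 1]), cell_y = as.integer(xy[, 2]),
                    n = as.integer(cnt), mean_fr = as.numeric(agg))
  attr(out, "rotation") <- pc$rotation
  attr(out, "center") <- pc$center
  attr(out, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  out
}
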