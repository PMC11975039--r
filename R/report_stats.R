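#' Chi-square test for phase bias of significant samples
#'
#' Goodness-of-fit chi-square of the observed counts of significant samples
#' per peri-reach phase against expectation proportional to
#' `expected_weights` (typically the number of tested samples per phase, so
#' the null is "significance spread evenly over tested time").
#'
#' @param counts named integer vector of observed counts per phase.
#' @param expected_weights nonnegative weights, same length (default equal).
#' @return list(statistic, df, p, expected).
#' @export
phase_bias_test <- function(counts, expected_weights = NULL) {
  counts <- as.numeric(counts)
  if (is.null(expected_weights)) expected_weights <- rep(1, length(counts))
  if (length(counts) < 2) stop("need at least 2 categories")
  pr <- expected_weights / sum(expected_weights)
  if (any(pr <= 0)) stop("expected counts must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, p = pr))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = unname(ht$expected))
}

#' Two-proportion z-test (equality of proportions)
#'
#' Standard two-sided two-proportion z-test with pooled variance.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list(z, p, p1, p2).
#' @export
proportions_test <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (p1 - p2) / se else 0
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two samples
#'
#' Two-sided rank-sum test with tie-corrected normal approximation (the
#' approximation is used for n > 20 per group; smaller samples use the exact
#' distribution when there are no ties).
#'
#' @param x,y numeric samples.
#' @return list(statistic [W], p).
#' @export
ranksum_compare <- function(x, y) {
  large <- length(x) > 20 || length(y) > 20
  ties <- anyDuplicated(c(x, y)) > 0
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, exact = !large && !ties, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Kernel density of modulation onset/end times on the peri-reach grid
#'
#' Gaussian KDE over event times (e.g. onsets of significant modulation
#' intervals), Silverman's rule-of-thumb bandwidth by default.
#'
#' @param times numeric event times.
#' @param bandwidth kernel bandwidth (default `stats::bw.nrd0`).
#' @param from,to evaluation range (defaults to range(times) +/- 3 bw).
#' @param n number of evaluation points (default 512).
#' @return data.frame(t, density).
#' @export
event_time_density <- function(times, bandwidth = NULL, from = NULL,
                               to = NULL, n = 512) {
  stopifnot(length(times) >= 1)
  if (is.null(bandwidth)) {
    bandwidth <- if (length(times) >= 2 && stats::sd(times) > 0)
      stats::bw.nrd0(times) else 0.05
  }
  if (is.null(from)) from <- min(times) - 3 * bandwidth
  if (is.null(to)) to <- max(times) + 3 * bandwidth
  d <- stats::density(times, bw = bandwidth, from = from, to = to, n = n)
  data.frame(t = d$x, density = d$y)
}

#' Summarize pipeline outputs into the headline report
#'
#' Tallies modulated / tuned / encoding units, the phase distribution of
#' significant modulation samples, positive-modulation proportion, optimal
#' lags, top Shapley groups and median adjusted R-squared per regressor set.
#'
#' @param modulation named list of `modulation_result` per unit (may be
#'   empty).
#' @param tuning named list of `tuning_result` per unit (or NULL).
#' @param encoding named list (per unit) of lists of `encoding_result` per
#'   regressor set (or NULL).
#' @param grid a `peri_reach_grid` giving the phase layout (or NULL).
#' @return a nested list ready for JSON serialization.
#' @export
summarize_session <- function(modulation, tuning = NULL, encoding = NULL,
                              grid = NULL) {
  rep_out <- list()
  n_units <- length(modulation)
  rep_out$n_units <- n_units
  if (n_units > 0) {
    mod_flags <- vapply(modulation, `[[`, logical(1), "is_modulated")
    rep_out$pct_modulated_units <- 100 * mean(mod_flags)
    phases <- if (!is.null(grid)) grid$phase else NULL
    if (!is.null(phases)) {
      sig_counts <- c(pre = 0, reach_first = 0, reach_second = 0, post = 0)
      pos <- 0; tot <- 0
      for (m in modulation) {
        if (!nrow(m$intervals)) next
        for (i in seq_len(nrow(m$intervals))) {
          idx <- m$intervals$start[i]:m$intervals$end[i]
          ph <- table(factor(phases[idx], names(sig_counts)))
          sig_counts <- sig_counts + as.numeric(ph)
          pos <- pos + if (m$intervals$sign[i] > 0) length(idx) else 0
          tot <- tot + length(idx)
        }
      }
      rep_out$significant_sample_counts <- as.list(sig_counts)
      rep_out$pct_positive_samples <- if (tot > 0) 100 * pos / tot else NA
      reach_n <- sig_counts[["reach_first"]] + sig_counts[["reach_second"]]
      rep_out$pct_samples_in_reach <- if (tot > 0) 100 * reach_n / tot else NA
      if (reach_n > 0) {
        rep_out$pct_second_half <-
          100 * sig_counts[["reach_second"]] / reach_n
        rep_out$phase_split_test <- phase_bias_test(
          c(sig_counts[["reach_first"]], sig_counts[["reach_second"]]))
      }
    }
  }
  if (!is.null(tuning) && length(tuning)) {
    tuned <- vapply(tuning, `[[`, logical(1), "is_tuned")
    rep_out$pct_tuned_units <- 100 * mean(tuned)
  }
  if (!is.null(encoding) && length(encoding)) {
    for (set in unique(unlist(lapply(encoding, names)))) {
      res <- lapply(encoding, `[[`, set)
      res <- res[!vapply(res, is.null, logical(1))]
      sig <- vapply(res, function(r) r$null$significant, logical(1))
      adj <- vapply(res, function(r) r$fit$opt_adj_r2, numeric(1))
      lag <- vapply(res, function(r) r$fit$opt_lag_s, numeric(1))
      top <- vapply(res, function(r)
        names(which.max(r$shapley$group_values)), character(1))
      rep_out[[set]] <- list(
        pct_significant_units = 100 * mean(sig),
        median_adj_r2_significant = if (any(sig))
          stats::median(adj[sig]) else NA,
        mean_r2_significant = if (any(sig)) {
          r2s <- vapply(res, function(r) r$fit$opt_r2, numeric(1))
          mean(r2s[sig])
        } else NA,
        optimal_lags_ms = as.list(1000 * lag),
        top_group_tally = as.list(table(top[sig]))
      )
    }
  }
  rep_out
}
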