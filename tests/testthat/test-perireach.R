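test_that("the stretched grid has the prescribed layout for any duration", {
  s <- std_session()
  st <- generate_spikes(s$traj, unit_ground_truth(20L, baseline_rate = 20),
                        seed = 6)
  r50 <- std_rate(st, 50, id = 20)
  re <- s$reaches[s$reaches$valid, ]
  # force two very different durations into the table
  re2 <- re[1:4, ]
  re2$t_end[1] <- re2$t_start[1] + 0.4
  re2$t_end[2] <- re2$t_start[2] + 0.8
  re2$duration <- re2$t_end - re2$t_start
  g <- build_grid(r50, re2)
  expect_equal(dim(g$fr), c(4, 380))
  expect_equal(sum(g$phase == "pre"), 150)
  expect_equal(sum(g$phase == "reach_first"), 40)
  expect_equal(sum(g$phase == "reach_second"), 40)
  expect_equal(sum(g$phase == "post"), 150)
  expect_equal(sum(g$mask), 160)
  # in-reach spacing = duration / 79 under the inclusive-endpoint convention
  expect_equal(g$grid_time[151], 0)
  expect_equal(mean(diff(g$grid_time[151:230])), mean(re2$duration) / 79,
               tolerance = 1e-9)
})

test_that("a constant-rate unit yields a constant grid and degenerate
           baseline", {
  s <- std_session()
  r <- fractional_interval_rate(seq(0.25, diff(s$span), by = 0.05) + s$span[1],
                                span = s$span)
  g <- build_grid(smooth_rate(r, 50), s$reaches)
  expect_lt(diff(range(g$fr)), 1e-6)
  b <- shuffle_baseline(smooth_rate(r, 50), nrow(g$fr), 2000, seed = 1)
  expect_lt(diff(range(b)), 1e-6)
  m <- test_modulation(g, b)
  expect_true(m$degenerate)
  expect_false(m$is_modulated)
  expect_true(all(m$sign == 0))
})

test_that("shuffle baseline spread shrinks as 1/sqrt(n) and is seed-stable", {
  s <- std_session()
  st <- generate_spikes(s$traj, unit_ground_truth(21L, baseline_rate = 20),
                        seed = 7)
  r50 <- std_rate(st, 50, id = 21)
  b10 <- shuffle_baseline(r50, 10, 4000, seed = 2)
  b40 <- shuffle_baseline(r50, 40, 4000, seed = 3)
  expect_equal(sd(b10) / sd(b40), 2, tolerance = 0.25)
  expect_identical(b10, shuffle_baseline(r50, 10, 4000, seed = 2))
})

test_that("injected in-reach rate increases are detected with the right sign
           and phase", {
  s <- std_session()
  re <- s$reaches[s$reaches$valid, ]
  # +15 spikes/s during the second half of every reach
  rate <- rep(20, length(s$traj$t))
  for (k in seq_len(nrow(re))) {
    mid <- (re$t_start[k] + re$t_end[k]) / 2
    rate[s$traj$t >= mid & s$traj$t <= re$t_end[k]] <- 35
  }
  st <- thin_spikes(s$traj$t, rate, seed = 31)
  r50 <- std_rate(st, 50, id = 22)
  g <- build_grid(r50, re)
  b <- shuffle_baseline(r50, nrow(g$fr), 10000, seed = 4)
  m <- test_modulation(g, b)
  expect_true(m$is_modulated)
  pos <- m$intervals[m$intervals$sign > 0 & m$intervals$in_window, ]
  expect_gt(nrow(pos), 0)
  hit <- unlist(Map(seq, pos$start, pos$end))
  expect_gt(sum(g$phase[hit] == "reach_second"), 0)
})

test_that("modulation p-values are monotone in the observed mean", {
  set.seed(8)
  base <- rnorm(5000, 20, 2)
  obs <- seq(10, 30, length.out = 50)
  sb <- sort(base)
  nb <- length(sb)
  p_hi <- (nb - findInterval(obs, sb, left.open = TRUE) + 1) / (nb + 1)
  expect_true(all(diff(p_hi) <= 0))
})

test_that("the per-timepoint Kruskal-Wallis matches stats::kruskal.test and
           reduces to the rank-sum test for two groups", {
  set.seed(10)
  g <- factor(rep(1:3, c(12, 15, 9)))
  for (i in 1:5) {
    x <- round(rnorm(36, sd = 2), 1) # induces ties
    ref <- kruskal.test(x, g)$p.value
    got <- vimreach:::kw_pvalue(x, split(seq_along(g), g),
                                table(g), 36, 2)
    expect_equal(got, ref, tolerance = 1e-12)
  }
  g2 <- factor(rep(1:2, c(14, 12)))
  x2 <- round(rnorm(26), 1)
  kw <- vimreach:::kw_pvalue(x2, split(seq_along(g2), g2), table(g2), 26, 1)
  ws <- wilcox.test(x2[g2 == 1], x2[g2 == 2], exact = FALSE,
                    correct = FALSE)$p.value
  expect_equal(kw, ws, tolerance = 1e-10)
})

test_that("directional tuning detects direction-gain units and respects
           group-size preconditions", {
  s <- std_session()
  u <- unit_ground_truth(23L, baseline_rate = 18, direction_gain = 14,
                         preferred_direction = c(1, 0.5, 0))
  st <- generate_spikes(s$traj, u, seed = 9)
  g <- build_grid(std_rate(st, 50, id = 23), s$reaches)
  tun <- test_directional_tuning(g)
  expect_true(tun$is_tuned)
  expect_error(test_directional_tuning(g, labels = rep(1, nrow(g$fr))),
               "direction groups")
})

test_that("permuting direction labels calibrates the per-timepoint
           Kruskal-Wallis p-values", {
  s <- std_session()
  u <- unit_ground_truth(24L, baseline_rate = 18, direction_gain = 14,
                         preferred_direction = c(0, 1, 0))
  st <- generate_spikes(s$traj, u, seed = 12)
  g <- build_grid(std_rate(st, 50, id = 24), s$reaches)
  set.seed(13)
  ps <- unlist(lapply(1:30, function(i)
    test_directional_tuning(g, labels = sample(g$reaches$direction_label))$p))
  # per-timepoint false-positive rate matches alpha under label exchange
  # (unit-level rates after the contiguity rule are inflated by the serial
  # dependence of neighboring timepoints; see the methods vignette)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.025)
  expect_lt(abs(mean(ps < 0.2) - 0.2), 0.05)
})

test_that("spatial heatmaps localize a parked fingertip and are rotation
           equivariant", {
  t <- (0:599) / 120
  parked <- make_traj(t, cbind(31, -7, 2)[rep(1, 600), ])
  r <- fractional_interval_rate(seq(0.2, 4.8, by = 0.05), span = c(0, 5))
  f <- differentiate(parked)
  hm <- spatial_heatmap(f, smooth_rate(r, 50))
  expect_equal(nrow(hm), 1)
  expect_equal(hm$n, 600)

  s <- std_session()
  st <- generate_spikes(s$traj, unit_ground_truth(25L, baseline_rate = 20),
                        seed = 14)
  r50 <- std_rate(st, 50, id = 25)
  hm1 <- spatial_heatmap(s$f50, r50)
  th <- 1.1
  R <- rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  pos_r <- cbind(s$f50$pos_x, s$f50$pos_y, s$f50$pos_z) %*% t(R)
  f_r <- s$f50
  f_r$pos_x <- pos_r[, 1]; f_r$pos_y <- pos_r[, 2]; f_r$pos_z <- pos_r[, 3]
  hm2 <- spatial_heatmap(f_r, r50)
  # the multiset of occupied-cell values is invariant up to in-plane
  # rotation/reflection; compare occupancy-weighted rate summaries
  expect_equal(sum(hm1$n), sum(hm2$n))
  expect_equal(sum(hm1$mean_fr * hm1$n), sum(hm2$mean_fr * hm2$n),
               tolerance = 1e-6)
  # planar sessions: the PC plane captures the display plane
  expect_lt(attr(hm1, "var_explained")[3], 0.05)
})
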