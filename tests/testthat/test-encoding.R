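test_that("the regression design has the documented shape and normalization", {
  s <- std_session()
  des <- s$design
  expect_identical(colnames(des$X),
                   names(regressor_groups("kinematics_plus_error")))
  prep <- vimreach:::prepare_design(des, "kinematics_only")
  expect_equal(ncol(prep$X), 12)
  expect_lt(max(abs(colMeans(prep$X))), 1e-12)
  expect_equal(unname(apply(prep$X, 2, sd)), rep(1, 12), tolerance = 1e-12)
  prep2 <- vimreach:::prepare_design(des, "kinematics_plus_error")
  expect_equal(ncol(prep2$X), 16)
})

test_that("error magnitude at Reach Start matches the task geometry", {
  cl <- clean_session()
  re <- curate_reaches(detect_reaches(cl$f0, cl$ev, cl$cfg))
  f15 <- compute_features(cl$traj, 15)
  des <- build_design(f15, re)
  rr <- re[re$valid, ]
  starts <- vapply(seq_len(nrow(rr)), function(k) {
    i <- which(des$reach == k)
    if (!length(i)) return(NA_real_)
    j <- i[which.min(abs(des$t[i] - rr$t_start[k]))]
    des$X[j, "err_mag"]
  }, numeric(1))
  # a straight 178 mm reach starts 178 mm from its goal position
  expect_equal(median(starts, na.rm = TRUE), 178, tolerance = 0.05 * 178)
})

test_that("window variants produce 500 ms samples around the anchors", {
  s <- std_session()
  for (w in c("start_centered_500ms", "end_centered_500ms")) {
    d <- build_design(s$f15, s$reaches, window = w)
    spans <- tapply(d$t, d$reach, function(x) diff(range(x)))
    expect_true(all(spans <= 0.5 + 1e-9))
    expect_gt(median(spans), 0.4)
  }
})

test_that("a noiseless linear velocity code is fit perfectly at its lag", {
  s <- std_session()
  # response manufactured from the design's own velocity columns
  rate_sig <- 30 + 0.05 * s$f15$vel_x - 0.03 * s$f15$vel_y
  dt <- 0.001
  grid <- seq(s$span[1], s$span[2], by = dt)
  rf <- structure(list(unit_id = 0, t0 = s$span[1], dt = dt,
                       rate = approx(s$traj$t, rate_sig,
                                     xout = grid[-1] - dt / 2, rule = 2)$y,
                       kernel_sd_ms = 0, normalized = FALSE),
                  class = "rate_function")
  fit0 <- lagged_regression(s$design, rf, "kinematics_only",
                            lags_s = seq(-0.1, 0.1, by = 1 / 120))
  expect_equal(fit0$opt_lag_s, 0)
  expect_gt(fit0$opt_r2, 0.999)
  # same code delayed by +3 kinematic samples -> optimal lag exactly +25 ms
  rf3 <- rf
  rf3$rate <- approx(grid[-1] - dt / 2 + 3 / 120, rf$rate,
                     xout = grid[-1] - dt / 2, rule = 2)$y
  fit3 <- lagged_regression(s$design, rf3, "kinematics_only",
                            lags_s = seq(-0.1, 0.1, by = 1 / 120))
  expect_equal(fit3$opt_lag_s, 3 / 120)
  expect_gt(fit3$opt_r2, 0.99)
})

test_that("adjusted R-squared applies the Ezekiel correction", {
  s <- std_session()
  st <- generate_spikes(s$traj, unit_ground_truth(30L, baseline_rate = 20),
                        seed = 16)
  r15 <- std_rate(st, 15, zscore = TRUE, id = 30)
  fit <- lagged_regression(s$design, r15, "kinematics_only",
                           lags_s = c(-0.05, 0, 0.05))
  manual <- 1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - fit$p - 1)
  expect_equal(fit$adj_r2, manual)
})

test_that("a zero circular shift reproduces the observed R-squared and seeds
           freeze the null", {
  s <- std_session()
  st <- generate_spikes(s$traj, unit_ground_truth(31L, baseline_rate = 20),
                        seed = 17)
  r15 <- std_rate(st, 15, zscore = TRUE, id = 31)
  fit <- lagged_regression(s$design, r15, "kinematics_only")
  idx0 <- rate_bin_index(r15, fit$prep$t)
  base_shift <- as.integer(round(fit$opt_lag_s / r15$dt))
  direct <- vimreach:::r2_for_shifts(fit$prep$Q, r15$rate, idx0, base_shift)
  expect_equal(direct, fit$opt_r2, tolerance = 1e-12)
  n1 <- circular_shift_null(fit, r15, n_shifts = 200, seed = 5)
  n2 <- circular_shift_null(fit, r15, n_shifts = 200, seed = 5)
  expect_identical(n1$null_r2, n2$null_r2)
})

test_that("the FFT shift curve agrees with direct refits", {
  s <- std_session()
  st <- generate_spikes(s$traj, unit_ground_truth(32L, baseline_rate = 20),
                        seed = 18)
  r15 <- std_rate(st, 15, zscore = TRUE, id = 32)
  fit <- lagged_regression(s$design, r15, "kinematics_only")
  curve <- vimreach:::r2_shift_curve(fit$prep, r15)
  idx0 <- rate_bin_index(r15, fit$prep$t)
  set.seed(19)
  shifts <- c(0L, 1L, sample.int(length(curve) - 1L, 15))
  direct <- vimreach:::r2_for_shifts(fit$prep$Q, r15$rate, idx0, shifts)
  expect_equal(curve[shifts + 1], direct, tolerance = 1e-6)
})

test_that("Shapley values satisfy efficiency, symmetry, orthogonality and
           order invariance", {
  set.seed(20)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("x", 1:6)
  y <- X %*% c(1, -2, 0.5, 0, 1, 0.2) + rnorm(n, sd = 2)
  sh <- shapley_decompose(X, y)
  expect_equal(sum(sh$values), sh$full_r2, tolerance = 1e-10)
  expect_equal(sh$full_r2, summary(lm(y ~ X))$r.squared, tolerance = 1e-10)

  # orthogonal columns: contribution_i = squared simple correlation
  # (orthogonalize after centering so the correlation matrix is exactly I)
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 5), n, 5), scale = FALSE)))
  colnames(Q) <- paste0("q", 1:5)
  yq <- Q %*% c(2, -1, 3, 0, 0.5) + rnorm(n)
  shq <- shapley_decompose(Q, yq)
  expect_equal(unname(shq$values), as.numeric(cor(yq, Q))^2,
               tolerance = 1e-6)

  # two identical columns carrying all signal share their contribution
  Z <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  yz <- X[, 1] * 2 + rnorm(n, sd = 0.5)
  shz <- shapley_decompose(Z, yz)
  expect_equal(shz$values[["a"]], shz$values[["b"]], tolerance = 1e-10)

  # column order must not matter
  perm <- c(4, 1, 6, 2, 5, 3)
  shp <- shapley_decompose(X[, perm], y)
  expect_equal(shp$values[colnames(X)], sh$values[colnames(X)],
               tolerance = 1e-10)
})

test_that("Gram-matrix subset R-squared equals refit-on-raw-samples
           R-squared", {
  set.seed(21)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5) %*% matrix(rnorm(25), 5, 5) # collinear-ish
  colnames(X) <- paste0("x", 1:5)
  y <- X %*% rnorm(5) + rnorm(n, sd = 3)
  sh <- shapley_decompose(X, y)
  for (S in list(1L, c(2L, 4L), c(1L, 3L, 5L), 1:5)) {
    ref <- summary(lm(y ~ X[, S, drop = FALSE]))$r.squared
    Xs <- scale(X); ys <- as.numeric(scale(y))
    C <- crossprod(Xs) / (n - 1); b <- crossprod(Xs, ys) / (n - 1)
    got <- sum(b[S] * solve(C[S, S], b[S]))
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("group contributions sum member columns and error groups never
           reduce in-sample fit", {
  s <- std_session()
  u <- unit_ground_truth(33L, baseline_rate = 20,
                         weights = c(err_x = 5, err_y = 5), true_lag_ms = 0)
  st <- generate_spikes(s$traj, u, seed = 22, features = s$feats)
  r15 <- std_rate(st, 15, zscore = TRUE, id = 33)
  fk <- lagged_regression(s$design, r15, "kinematics_only")
  fe <- lagged_regression(s$design, r15, "kinematics_plus_error")
  # nesting: the larger model can never fit worse, at every lag
  expect_true(all(fe$r2 >= fk$r2 - 1e-10))
  res <- encode_unit(s$design, r15, "kinematics_plus_error",
                     lags_s = seq(-0.2, 0.2, by = 1 / 120),
                     n_shifts = 200, seed = 23)
  gv <- res$shapley$group_values
  for (g in names(gv)) {
    members <- names(regressor_groups("kinematics_plus_error"))[
      regressor_groups("kinematics_plus_error") == g]
    expect_equal(gv[[g]], sum(res$shapley$values[members]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate designs are handled: zero-variance and oversized", {
  set.seed(24)
  X <- cbind(a = rnorm(100), b = rep(2, 100), c = rnorm(100))
  y <- X[, "a"] + rnorm(100)
  expect_warning(sh <- shapley_decompose(X, y), "zero-variance")
  expect_setequal(names(sh$values), c("a", "c"))
  Xbig <- matrix(rnorm(50 * 21), 50, 21)
  expect_error(shapley_decompose(Xbig, rnorm(50)), "20")
})
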