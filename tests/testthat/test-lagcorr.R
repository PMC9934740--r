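test_that("identical and shifted curves recover the exact lag", {
  set.seed(1)
  x <- cumsum(rnorm(40))^2
  same <- lagged_crosscorr(x, x)
  expect_equal(same$mcc, 1, tolerance = 1e-12)
  expect_identical(same$lag_frames, 0L)

  # y = x delayed by 2 frames: mcc 1 on the overlap, lag +2
  truth <- phantom_truth("delay_line")
  cur <- simulate_roi_curves(truth, noise_sd = 0)
  y2 <- c(rep(cur$signal[1, 1], 2), head(cur$signal[, 1], -2))
  pr <- lagged_crosscorr(cur$signal[, 1], y2, max_lag_frames = 5,
                         frame_interval = 2.5)
  expect_identical(pr$lag_frames, 2L)
  expect_equal(pr$lag, 5)
  expect_equal(pr$mcc, 1, tolerance = 1e-9)
})

test_that("the documented small example matches the brute-force search", {
  x <- c(0, 1, 2, 1, 0, 0); y <- c(0, 0, 1, 2, 1, 0)
  pr <- lagged_crosscorr(x, y, max_lag_frames = 2, min_overlap = 3)
  bf <- brute_force_lagcorr(x, y, max_lag = 2, min_overlap = 3)
  expect_equal(pr$mcc, bf$mcc, tolerance = 1e-12)
  expect_equal(pr$lag_frames, bf$lag)
  expect_identical(pr$lag_frames, 1L)
})

test_that("lagged_crosscorr matches the brute-force oracle on random pairs", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(8:64, 1)
    L <- sample.int(n %/% 3, 1)
    mo <- max(3, n - 2 * L)
    x <- rnorm(n) + sin(seq_len(n) / 3) * runif(1, 0, 3)
    y <- rnorm(n) + cos(seq_len(n) / 4) * runif(1, 0, 3)
    pr <- lagged_crosscorr(x, y, max_lag_frames = L, min_overlap = mo)
    bf <- brute_force_lagcorr(x, y, max_lag = L, min_overlap = mo)
    expect_equal(pr$mcc, bf$mcc, tolerance = 1e-12)
    expect_equal(pr$lag_frames, bf$lag)
  }
})

test_that("mcc is invariant under positive affine rescaling", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  a <- lagged_crosscorr(x, y, 6)
  b <- lagged_crosscorr(3.7 * x + 11, y, 6)
  c <- lagged_crosscorr(x, 0.2 * y - 4, 6)
  expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
  expect_equal(a$lag_frames, b$lag_frames)
  expect_equal(a$mcc, c$mcc, tolerance = 1e-12)
})

test_that("zero-variance overlaps are excluded or rejected", {
  expect_error(lagged_crosscorr(rep(1, 10), rnorm(10)), "undefined")
  # linear ramps tie at every lag; tie-break returns lag 0
  pr <- lagged_crosscorr(as.numeric(1:20), as.numeric(1:20), 5)
  expect_identical(pr$lag_frames, 0L)
})

test_that("nonnegative lag mode restricts the search window", {
  set.seed(7)
  x <- rnorm(30)
  y <- c(rnorm(3), head(x, -3))   # y lags x by 3
  pr <- lagged_crosscorr(x, y, 8, lag_mode = "nonnegative")
  expect_true(all(as.integer(names(pr$cc_profile)) >= 0))
  expect_identical(pr$lag_frames, 3L)
})

test_that("matrix invariants hold exactly and match pair calls", {
  truth <- phantom_truth("four_cluster", seed = 8)
  cur <- subtract_baseline(simulate_roi_curves(truth, noise_sd = 10, seed = 8))
  lc <- crosscorr_matrix(cur)
  expect_equal(lc$mcc, t(lc$mcc))
  expect_equal(lc$lag, -t(lc$lag))
  expect_equal(diag(lc$mcc), rep(1, 20), ignore_attr = TRUE)
  expect_equal(diag(lc$lag), rep(0, 20), ignore_attr = TRUE)
  i <- 3; j <- 11
  pr <- lagged_crosscorr(cur$signal[, i], cur$signal[, j],
                         frame_interval = frame_interval(cur))
  expect_equal(lc$mcc[i, j], pr$mcc)
  expect_equal(lc$lag[i, j], pr$lag)
})

test_that("three identical curves give unit mcc and zero lag", {
  truth <- synthetic_truth(kinetic_params(n_stages = c(2, 2, 2),
                                          rate_const = 0.3))
  cur <- simulate_roi_curves(truth, noise_sd = 0)
  lc <- crosscorr_matrix(cur)
  expect_equal(lc$mcc, matrix(1, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(lc$lag == 0))
})

test_that("noise-free planted lags are recovered exactly", {
  truth <- phantom_truth("delay_line")
  cur <- subtract_baseline(simulate_roi_curves(truth, noise_sd = 0))
  lc <- crosscorr_matrix(cur)
  expect_equal(lc$lag, truth$true_lag_matrix, tolerance = 1e-12)
})

test_that("cascade-depth differences are recovered within one frame", {
  # extra stages at 0.4/min add exactly one 2.5-min frame of mean delay
  p <- kinetic_params(n_stages = c(2L, 3L, 5L), rate_const = 0.4)
  truth <- synthetic_truth(p)
  cur <- subtract_baseline(simulate_roi_curves(truth, noise_sd = 0))
  lc <- crosscorr_matrix(cur)
  expect_true(all(abs(lc$lag - truth$true_lag_matrix) <= 2.5))
})

test_that("dissimilarity is 1 - mcc with no clamping", {
  truth <- phantom_truth("two_cluster", seed = 4)
  cur <- subtract_baseline(simulate_roi_curves(truth, noise_sd = 5, seed = 4))
  lc <- crosscorr_matrix(cur)
  d <- to_dissimilarity(lc)
  expect_equal(unclass(d), 1 - lc$mcc, ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
  lc$mcc[1, 2] <- lc$mcc[2, 1] <- -0.2
  expect_equal(to_dissimilarity(lc)[1, 2], 1.2)
  lc$mcc[1, 2] <- lc$mcc[2, 1] <- 0.6
  expect_equal(to_dissimilarity(lc)[1, 2], 0.4)
})

test_that("the combined mCC/lag table mirrors both triangles", {
  truth <- phantom_truth("delay_line")
  cur <- subtract_baseline(simulate_roi_curves(truth, noise_sd = 0))
  lc <- crosscorr_matrix(cur)
  tab <- mcc_lag_table(lc)
  expect_equal(tab[2, 1], lc$mcc[2, 1])
  expect_equal(tab[1, 2], lc$lag[1, 2])
  expect_true(all(is.na(diag(tab))))
})
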