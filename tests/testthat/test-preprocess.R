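make_series <- function(nx = 5, ny = 4, nz = 3, nt = 12, seed = 1,
                        n_baseline = 2) {
  set.seed(seed)
  dynamic_series(array(rnorm(nx * ny * nz * nt, 100, 5), c(nx, ny, nz, nt)),
                 time = (seq_len(nt) - 0.5) * 2.5,
                 n_baseline_frames = n_baseline)
}

make_labels <- function(dm, n_roi = 4, seed = 2) {
  set.seed(seed)
  lab <- array(sample.int(n_roi + 1L, prod(dm), replace = TRUE) - 1L, dm)
  label_map(lab)
}

test_that("ROI means match a per-voxel brute-force loop", {
  s <- make_series()
  lm <- make_labels(dim(s$data)[1:3])
  cur <- extract_roi_timecourses(s, lm)
  for (k in seq_along(cur$roi_id)) {
    lab <- cur$roi_id[k]
    for (t in seq_along(s$time)) {
      acc <- 0; nv <- 0
      for (x in 1:dim(s$data)[1]) for (y in 1:dim(s$data)[2])
        for (z in 1:dim(s$data)[3])
          if (lm$labels[x, y, z] == lab) {
            acc <- acc + s$data[x, y, z, t]; nv <- nv + 1
          }
      expect_equal(unname(cur$signal[t, k]), acc / nv, tolerance = 1e-12)
    }
  }
})

test_that("spatially uniform frames give every ROI the frame value", {
  dm <- c(4, 4, 2); nt <- 5
  vals <- c(10, 20, 30, 40, 50)
  arr <- array(rep(vals, each = prod(dm)), c(dm, nt))
  s <- dynamic_series(arr, time = 1:nt, n_baseline_frames = 1)
  lm <- make_labels(dm, n_roi = 3)
  cur <- extract_roi_timecourses(s, lm)
  for (k in seq_len(ncol(cur$signal))) expect_equal(cur$signal[, k], vals)
})

test_that("temporal averaging reproduces the 312 -> 52 frame grouping", {
  acq <- default_acquisition("t2_water")
  truth <- phantom_truth("delay_line")
  cur <- simulate_roi_curves(truth, acq = acq, noise_sd = 0)
  avg <- temporal_average(cur, 6)
  expect_equal(n_frames(avg), 52)
  expect_equal(unique(round(diff(avg$time), 10)), 2.5)
  expect_equal(avg$n_baseline_frames, 2L)
  # block means check against direct computation
  expect_equal(unname(avg$signal[1, 1]), mean(cur$signal[1:6, 1]),
               tolerance = 1e-12)
  expect_equal(avg$time[52], mean(cur$time[307:312]), tolerance = 1e-12)
})

test_that("temporal averaging drops trailing remainders and keeps identity", {
  cur <- roi_curves(1:13, matrix(rnorm(26), 13, 2), n_baseline_frames = 3)
  avg <- temporal_average(cur, 6)
  expect_equal(n_frames(avg), 2)
  expect_equal(avg$n_baseline_frames, 0L)
  expect_identical(temporal_average(cur, 1), cur)
  expect_error(temporal_average(cur, 14), "exceeds")
})

test_that("extract then average equals average then extract", {
  s <- make_series(nt = 13)
  lm <- make_labels(dim(s$data)[1:3])
  a <- temporal_average(extract_roi_timecourses(s, lm), 3)
  b <- extract_roi_timecourses(temporal_average(s, 3), lm)
  expect_equal(a$signal, b$signal, tolerance = 1e-12)
  expect_equal(a$time, b$time, tolerance = 1e-12)
})

test_that("baseline subtraction recenters and applies polarity", {
  cur <- roi_curves(1:10, matrix(c(rep(7, 10), 1:10), 10, 2),
                    n_baseline_frames = 4)
  ds <- subtract_baseline(cur)
  expect_equal(ds$signal[, 1], rep(0, 10))
  expect_equal(ds$signal[1:4, 2], (1:4) - 2.5)

  # polarity -1: a signal-decreasing tracer yields positive uptake
  truth <- tracer_presets("fast_extensive")
  cur2 <- simulate_roi_curves(truth, noise_sd = 0)
  expect_lt(min(cur2$signal - 100), -10)       # raw signal drops
  ds2 <- subtract_baseline(cur2)
  post <- ds2$signal[-(1:2), ]
  expect_gt(max(post), 10)
  expect_gt(min(post), -1e-6)                  # uptake positive everywhere
})

test_that("input-function normalization scales correctly and safely", {
  truth <- phantom_truth("four_cluster", seed = 2)
  cur <- subtract_baseline(simulate_roi_curves(truth, noise_sd = 5, seed = 2))
  nrm <- normalize_by_input(cur, reference_roi = 1)
  expect_equal(max(nrm$signal[, 1]), 1)
  expect_equal(nrm$reference_max, max(cur$signal[, 1]))
  # doubling all raw signals leaves normalized curves unchanged
  cur2 <- cur; cur2$signal <- cur2$signal * 2
  nrm2 <- normalize_by_input(cur2, reference_roi = 1)
  expect_equal(nrm2$signal, nrm$signal, tolerance = 1e-12)
  expect_equal(nrm$signal, cur$signal / max(cur$signal[, 1]),
               tolerance = 1e-12)
  # flat reference: no detectable infusion
  flat <- subtract_baseline(roi_curves(1:10, matrix(5, 10, 2),
                                       n_baseline_frames = 2))
  expect_error(normalize_by_input(flat, 1), "non-positive")
  expect_error(normalize_by_input(cur, 99), "not present")
})

test_that("pairwise correlation is invariant under normalization", {
  truth <- phantom_truth("two_cluster", seed = 3)
  cur <- subtract_baseline(simulate_roi_curves(truth, noise_sd = 8, seed = 3))
  nrm <- normalize_by_input(cur, reference_roi = 1)
  expect_equal(cor(cur$signal), cor(nrm$signal), tolerance = 1e-12)
})

test_that("tMIP equals the per-voxel post-baseline maximum", {
  s <- make_series(nt = 8, n_baseline = 3)
  tm <- compute_tmip(s)
  dm <- dim(s$data)
  base <- apply(s$data[, , , 1:3, drop = FALSE], 1:3, mean)
  for (i in 1:3) for (j in 1:3) for (k in 1:2) {
    expect_equal(tm[i, j, k],
                 max(s$data[i, j, k, 4:8] - base[i, j, k]),
                 tolerance = 1e-12)
  }
  # monotone voxel: tMIP is the last-frame signal change
  arr <- array(rep(1:6, each = 8), c(2, 2, 2, 6))
  s2 <- dynamic_series(arr, 1:6, n_baseline_frames = 1)
  expect_equal(unique(as.vector(compute_tmip(s2))), 5)
  # all-baseline (constant) series: tMIP = 0
  s3 <- dynamic_series(array(7, c(2, 2, 2, 4)), 1:4, n_baseline_frames = 2)
  expect_equal(max(abs(compute_tmip(s3))), 0)
})
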