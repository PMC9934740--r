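test_that("simulation is deterministic given a seed", {
  truth <- phantom_truth("four_cluster", seed = 3)
  a <- simulate_roi_curves(truth, noise_sd = 10, seed = 42)
  b <- simulate_roi_curves(truth, noise_sd = 10, seed = 42)
  c <- simulate_roi_curves(truth, noise_sd = 10, seed = 43)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
})

test_that("identical parameters give identical noise-free curves", {
  p <- kinetic_params(n_stages = c(2, 2), rate_const = 0.3)
  cur <- simulate_roi_curves(synthetic_truth(p), noise_sd = 0)
  expect_identical(cur$signal[, 1], cur$signal[, 2])
})

test_that("an extra cascade stage strictly delays the noise-free peak", {
  tm <- seq(0, 200, by = 0.05)
  prot <- infusion_protocol()
  for (k in 1:4) {
    a <- tracer_unit_response(tm, prot, n_stages = k, rate_const = 0.4)
    b <- tracer_unit_response(tm, prot, n_stages = k + 1L, rate_const = 0.4)
    expect_gt(tm[which.max(b)], tm[which.max(a)])
  }
})

test_that("ground-truth lags equal differences of mean transport delays", {
  truth <- phantom_truth("delay_line")
  expect_equal(truth$true_lag_matrix["lead", "lag1"], 2.5)
  expect_equal(truth$true_lag_matrix["lead", "lag3"], 7.5)
  expect_equal(truth$true_lag_matrix, -t(truth$true_lag_matrix))
  expect_true(all(diag(truth$true_lag_matrix) == 0))
  # cascade-depth route: one extra stage at 0.4/min adds 2.5 min
  p <- kinetic_params(n_stages = c(2L, 3L), rate_const = 0.4)
  tau <- transport_delay(p)
  expect_equal(tau[2] - tau[1], 2.5)
})

test_that("volume synthesis and ROI extraction are inverse at zero noise", {
  truth <- phantom_truth("four_cluster", seed = 5)
  labels <- ellipsoid_label_map(n_roi = 20, names = truth$params$roi_name)
  vol <- simulate_dynamic_volume(truth, labels, noise_sd = 0)
  cur_vol <- extract_roi_timecourses(vol, labels)
  cur_ref <- simulate_roi_curves(truth, noise_sd = 0)
  expect_equal(cur_vol$signal, cur_ref$signal, tolerance = 1e-12)
  expect_identical(cur_vol$roi_id, cur_ref$roi_id)
})

test_that("a single-voxel ROI's mean equals its voxel series", {
  lab <- array(0L, c(4, 4, 3))
  lab[2, 2, 2] <- 1L
  lm <- label_map(lab)
  truth <- synthetic_truth(kinetic_params(n_stages = 1, rate_const = 0.5))
  vol <- simulate_dynamic_volume(truth, lm, noise_sd = 3, seed = 9)
  cur <- extract_roi_timecourses(vol, lm)
  expect_equal(cur$signal[, 1], vol$data[2, 2, 2, ])
})

test_that("noisy ROI means stay within the CLT bound of the true curve", {
  truth <- phantom_truth("four_cluster", seed = 6)
  labels <- ellipsoid_label_map(n_roi = 20, names = truth$params$roi_name)
  noise <- 8
  vol <- simulate_dynamic_volume(truth, labels, noise_sd = noise, seed = 10)
  cur <- extract_roi_timecourses(vol, labels)
  ref <- simulate_roi_curves(truth, noise_sd = 0)
  nv <- table(labels$labels[labels$labels > 0])
  dev <- vapply(seq_along(cur$roi_id), function(k) {
    se <- noise / sqrt(nv[[as.character(cur$roi_id[k])]])
    abs(cur$signal[, k] - ref$signal[, k]) / se
  }, numeric(n_frames(cur)))
  # CLT: ~99.7% of standardized deviations within 3 se, none far outside
  expect_gte(mean(dev <= 3), 0.99)
  expect_lt(max(dev), 5)
})

test_that("labels without kinetic parameters are rejected", {
  truth <- phantom_truth("delay_line")   # 3 ROIs
  labels <- ellipsoid_label_map(n_roi = 5)
  expect_error(simulate_dynamic_volume(truth, labels), "no kinetic parameters")
})

test_that("parameter validation catches bad values", {
  expect_error(kinetic_params(0, 0.5), "n_stages")
  expect_error(kinetic_params(1, -1), "rate_const")
  expect_error(kinetic_params(1, 0.5, amplitude = -2), "amplitude")
  expect_error(kinetic_params(1, 0.5, mix2 = 1), "mix2")
  expect_error(simulate_roi_curves(phantom_truth("delay_line"),
                                   noise_sd = -1), "noise_sd")
})

test_that("agent presets reproduce the qualitative tracer regimes", {
  fast <- tracer_presets("fast_extensive")
  expect_true(all(fast$params$polarity == -1L))
  conf <- tracer_presets("csf_confined")
  deep_amp <- conf$params$amplitude[grepl("^deep", conf$params$roi_name)]
  csf_amp <- conf$params$amplitude[conf$params$roi_name == "cisterna_magna"]
  expect_true(all(deep_amp < 0.05 * csf_amp))
  slow <- tracer_presets("slow_parenchymal")
  tau <- transport_delay(slow$params)
  expect_gt(min(tau[grepl("^deep", slow$params$roi_name)]),
            max(tau[grepl("^ventral|cisterna", slow$params$roi_name)]))
})
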