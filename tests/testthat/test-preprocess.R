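test_that("low-pass filter preserves DC and the passband, kills the stopband", {
  expect_equal(lowpass_filter(rep(3.7, 200), 6, 120), rep(3.7, 200),
               tolerance = 1e-9)
  t <- seq(0, 5, by = 1 / 120)
  mid <- 150:450
  # squared 2nd-order Butterworth magnitude: (1 + (f/fc)^4)^-1
  # f = 1, fc = 6 -> 0.9992; f = 30 -> 0.0016
  s1 <- lowpass_filter(sin(2 * pi * 1 * t), 6, 120)
  expect_gt(max(abs(s1[mid])), 0.99)
  s30 <- lowpass_filter(sin(2 * pi * 30 * t), 6, 120)
  expect_lt(max(abs(s30[mid])), 0.05)
})

test_that("filter rejects cutoffs at or above Nyquist", {
  expect_error(lowpass_filter(rnorm(100), 60, 120),
               class = "reachkin_error_invalid_argument")
  expect_error(lowpass_filter(rnorm(100), 0, 120),
               class = "reachkin_error_invalid_argument")
})

test_that("speed profile is exact for stationary and uniform motion", {
  still <- matrix(5, nrow = 50, ncol = 3)
  expect_equal(speed_profile(still, 120), rep(0, 50))
  # 2 cm per frame along x at 120 frames/s -> 240 cm/s everywhere
  mov <- cbind(seq(0, by = 2, length.out = 50), 0, 0)
  expect_equal(speed_profile(mov, 120), rep(240, 50))
  expect_error(speed_profile(mov[1:2, ], 120),
               class = "reachkin_error_insufficient_data")
})

test_that("speed profile recovers the analytic minimum-jerk peak", {
  mj <- min_jerk_profile(30, 1, 120)
  sp <- speed_profile(cbind(mj$position, 0, 0), 120)
  expect_equal(max(sp), 56.25, tolerance = 0.005)
})

test_that("movement onset sits at the analytic threshold crossing", {
  # solve 30 tau^2 (1 - tau)^2 = 0.05 * 1.875 -> tau = 0.0592
  mj <- min_jerk_profile(30, 1, 1000)
  sp <- speed_profile(mj$position, 1000)
  seg <- detect_reach_bounds(sp, 0.05, phase = "outbound")
  onset_frac <- (seg$onset_frame - 1) / (length(sp) - 1)
  expect_equal(onset_frac, 0.0592, tolerance = 0.01)
})

test_that("degenerate speed inputs raise typed errors", {
  expect_error(detect_reach_bounds(rep(0, 100), 0.05),
               class = "reachkin_error_no_movement")
})

test_that("segmentation is invariant to uniform speed scaling", {
  mj <- min_jerk_profile(30, 1, 500)
  sp <- speed_profile(mj$position, 500)
  s1 <- detect_reach_bounds(sp, 0.05, phase = "outbound")
  s2 <- detect_reach_bounds(sp * 17.3, 0.05, phase = "outbound")
  expect_identical(unclass(s1), unclass(s2))
})

test_that("full-cycle segmentation brackets the generating submovement windows", {
  trial <- synth_reach_trial(clean_config(n_submovements = 2,
                                          movement_duration = 1.5),
                             test_geom, 4)
  fs <- trial$sample_rate
  mk <- trial$markers$RMCP2
  sp <- speed_profile(mk, fs)
  seg <- detect_reach_bounds(sp, 0.05, "full_cycle", positions = mk)
  win <- truth_segment(trial)
  # the detected bounds sit at the 5% crossings of the first/last
  # submovement: tau* = 0.0592 of one submovement's duration inside the
  # generating window
  sub_frames <- 0.45 * 1.5 * fs
  expect_equal(seg$onset_frame, win$onset_frame + 0.0592 * sub_frames - 1,
               tolerance = 3, ignore_attr = TRUE)
  expect_equal(seg$end_frame, win$end_frame - 0.0592 * sub_frames + 1,
               tolerance = 3, ignore_attr = TRUE)
  # and the segment stays inside the movement window
  expect_gte(seg$onset_frame, win$onset_frame)
  expect_lte(seg$end_frame, win$end_frame + 1)
})

test_that("detected movement time converges to the generating duration as the threshold shrinks", {
  trial <- synth_reach_trial(clean_config(movement_duration = 1.5),
                             test_geom, 7)
  mts <- vapply(c(0.10, 0.05, 0.02), function(f) {
    reach_parameters(trial, test_geom, threshold_fraction = f)$MT
  }, numeric(1))
  expect_true(all(diff(mts) > 0))
  expect_true(all(mts < trial$truth$true_MT))
  expect_lt(trial$truth$true_MT - mts[3], 0.1 * trial$truth$true_MT)
})
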