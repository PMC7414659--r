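test_that("movement time is segment length over sample rate", {
  seg <- structure(list(onset_frame = 1L, end_frame = 121L, phase = "outbound"),
                   class = "reach_segment")
  expect_equal(movement_time(seg, 120), 1.0)
  seg2 <- structure(list(onset_frame = 13L, end_frame = 301L, phase = "outbound"),
                    class = "reach_segment")
  expect_equal(movement_time(seg2, 120), 2.4)
})

test_that("trajectory directness is 1 for straight paths and pi/2 for a semicircle", {
  straight <- cbind(seq(0, 10, length.out = 200), 0, 0)
  expect_equal(trajectory_directness(straight, "outbound"), 1, tolerance = 1e-12)
  th <- seq(0, pi, length.out = 500)
  arc <- cbind(cos(th), sin(th), 0)
  expect_equal(trajectory_directness(arc, "outbound"), pi / 2, tolerance = 0.001)
})

test_that("simulated curved reach matches the quadrature path-length oracle", {
  trial <- synth_reach_trial(clean_config(path_curvature_gain = 0.3),
                             test_geom, 9)
  p <- reach_parameters(trial, test_geom, threshold_fraction = 0.02)
  truth_ci <- trial$truth$true_path_length / trial$truth$true_straight_distance
  expect_equal(p$CurvI, truth_ci, tolerance = 0.005)
})

test_that("peak velocity and its timing follow the analytic profile", {
  mj <- min_jerk_profile(30, 1, 1000)
  sp <- speed_profile(mj$position, 1000)
  expect_equal(time_to_peak_pct(sp), 50, tolerance = 0.2)
  expect_equal(peak_velocity(sp), 56.25, tolerance = 0.005 * 56.25)
  # asymmetric two-submovement profile peaks inside the larger (first) one
  sched <- tibble::tibble(onset = c(0, 0.55), amplitude = c(0.7, 0.3),
                          duration = c(0.45, 0.45))
  comp <- compose_submovements(sched, 10, 1, 500)
  expect_lt(which.max(comp$speed) / nrow(comp), 0.45)
})

test_that("velocity-peak count recovers the composed submovement count", {
  mj <- min_jerk_profile(30, 1, 120)
  sp <- speed_profile(mj$position, 120)
  expect_equal(count_velocity_peaks(sp, 120), 1L)
  for (k in 2:4) {
    comp <- compose_submovements(submovement_schedule(k), 30, 2, 120)
    expect_equal(count_velocity_peaks(comp$speed, 120), k)
  }
  expect_error(count_velocity_peaks(rep(0, 50), 120),
               class = "reachkin_error_no_movement")
})

test_that("velocity-peak count tolerates marker noise on simulated trials", {
  ks <- rep(1:4, 50)
  ok <- 0L
  for (i in seq_along(ks)) {
    cfg <- sim_config(n_submovements = ks[i], movement_duration = 1.25,
                      marker_noise_sd = 0.05, seed = 5000 + i)
    trial <- synth_reach_trial(cfg, test_geom, (i - 1) %% 12 + 1)
    p <- reach_parameters(trial, test_geom, phase = "outbound")
    if (p$NVP == ks[i]) ok <- ok + 1L
  }
  expect_gte(ok / length(ks), 0.95)
})

test_that("log dimensionless jerk matches the closed form and is scale invariant", {
  # DLJ of a minimum-jerk reach: 720 / 1.875^2 = 204.8
  mj <- min_jerk_profile(30, 1, 1000)
  sp <- speed_profile(mj$position, 1000)
  ldj <- log_dimensionless_jerk(sp, 1000)
  expect_equal(ldj, -log(204.8), tolerance = 0.01 * abs(log(204.8)))
  # amplitude rescaling: identical samples up to scale -> identical LDJ
  mj_a <- min_jerk_profile(60, 1, 1000)
  expect_equal(log_dimensionless_jerk(speed_profile(mj_a$position, 1000), 1000),
               ldj, tolerance = 1e-6)
  # duration rescaling on a matched sample grid
  mj_t <- min_jerk_profile(30, 2, 500)
  expect_equal(log_dimensionless_jerk(speed_profile(mj_t$position, 500), 500),
               ldj, tolerance = 1e-6)
  expect_error(log_dimensionless_jerk(rep(1, 5), 100),
               class = "reachkin_error_insufficient_data")
})

test_that("LDJ decreases monotonically with submovement count", {
  ldjs <- vapply(1:4, function(k) {
    comp <- compose_submovements(submovement_schedule(k), 30, 2, 120)
    log_dimensionless_jerk(comp$speed, 120)
  }, numeric(1))
  expect_true(all(diff(ldjs) < 0))
})

test_that("NVP and -LDJ rank a noiseless trial battery consistently", {
  battery <- purrr::map_dfr(1:50, function(i) {
    k <- (i - 1) %% 4 + 1
    cfg <- clean_config(n_submovements = k,
                        movement_duration = 1 + (i %% 5) * 0.2, seed = i)
    trial <- synth_reach_trial(cfg, test_geom, (i - 1) %% 12 + 1)
    reach_parameters(trial, test_geom)[, c("NVP", "LDJ")]
  })
  rs <- spearman_rho(battery$NVP, -battery$LDJ)$rho
  expect_gte(rs, 0.8)
})

test_that("all parameters are invariant to rigid motion of the marker set", {
  trial <- synth_reach_trial(clean_config(n_submovements = 2,
                                          path_curvature_gain = 0.2,
                                          trunk_translation = 5,
                                          trunk_rotation = 8),
                             test_geom, 3)
  p0 <- reach_parameters(trial, test_geom)
  ang <- 25 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  shift <- c(40, -15, 12)
  moved <- trial
  moved$markers <- lapply(trial$markers, function(m) {
    sweep(m %*% t(R), 2, shift, "+")
  })
  p1 <- reach_parameters(moved)  # no geometry: rotated target unknown
  for (v in kin_param_names) {
    expect_equal(p1[[v]], p0[[v]], tolerance = 1e-6, label = v)
  }
})
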