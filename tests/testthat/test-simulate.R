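test_that("panel geometry places 12 targets on the stated circle", {
  g <- test_geom
  d <- sqrt((g$targets$x - g$center[1])^2 + (g$targets$y - g$center[2])^2 +
              (g$targets$z - g$center[3])^2)
  expect_equal(d, rep(g$radius, 12))
  expect_setequal(g$targets$target, 1:12)
  # targets lie in the vertical panel plane
  expect_equal(g$targets$y, rep(g$center[2], 12))
  # start target at forearm distance from the center, toward the shoulder
  expect_equal(reachkin:::.norm3(g$start_position - g$center),
               g$forearm_length)
  expect_error(target_position(g, 13), class = "reachkin_error_invalid_argument")
})

test_that("trials are a pure function of configuration, geometry and target", {
  cfg <- sim_config(n_submovements = 2, marker_noise_sd = 0.1, seed = 11)
  t1 <- synth_reach_trial(cfg, test_geom, 5)
  t2 <- synth_reach_trial(cfg, test_geom, 5)
  expect_identical(t1$markers, t2$markers)
  t3 <- synth_reach_trial(sim_config(n_submovements = 2, marker_noise_sd = 0.1,
                                     seed = 12), test_geom, 5)
  expect_false(identical(t1$markers, t3$markers))
})

test_that("the noiseless endpoint touches the target at the outbound apex", {
  for (tgt in c(1, 4, 8, 12)) {
    trial <- synth_reach_trial(clean_config(path_curvature_gain = 0),
                               test_geom, tgt)
    d <- sqrt(rowSums((trial$markers$RMCP2 -
                         matrix(target_position(test_geom, tgt),
                                length(trial$time), 3, byrow = TRUE))^2))
    expect_lt(min(d), 1e-9)
  }
})

test_that("straight noiseless reaches have path length equal to the chord", {
  trial <- synth_reach_trial(clean_config(), test_geom, 2)
  expect_equal(trial$truth$true_path_length,
               trial$truth$true_straight_distance)
  expect_equal(trial$truth$true_trunk_excursion, 0)
  # curvature makes the generated path strictly longer than the chord
  curved <- synth_reach_trial(clean_config(path_curvature_gain = 0.2),
                              test_geom, 2)
  expect_gt(curved$truth$true_path_length, curved$truth$true_straight_distance)
})

test_that("injected trunk translation appears on the suprasternal-notch marker", {
  trial <- synth_reach_trial(clean_config(trunk_translation = 5), test_geom, 3)
  clav <- trial$markers$CLAV
  disp <- sqrt(rowSums((clav - matrix(clav[1, ], nrow(clav), 3,
                                      byrow = TRUE))^2))
  expect_equal(max(disp), 5, tolerance = 1e-9)
})

test_that("marker noise has the configured standard deviation", {
  # long static segment: rest padding of ~42 s gives ~10,000 still frames
  cfg <- sim_config(marker_noise_sd = 0.05, rest_pad = 41.5,
                    movement_duration = 1, seed = 21)
  trial <- synth_reach_trial(cfg, test_geom, 6)
  rest <- 1:(41.5 * 120)
  sds <- apply(trial$markers$CLAV[rest, ], 2, sd)
  expect_equal(unname(sds), rep(0.05, 3), tolerance = 0.05)
})

test_that("left-arm trials are mirrored but analyze identically", {
  cfg_r <- clean_config(n_submovements = 2, path_curvature_gain = 0.2,
                        trunk_translation = 4, trunk_rotation = 6)
  cfg_l <- sim_config(n_submovements = 2, path_curvature_gain = 0.2,
                      trunk_translation = 4, trunk_rotation = 6,
                      marker_noise_sd = 0, side = "left", seed = 1)
  tr_r <- synth_reach_trial(cfg_r, test_geom, 4)
  tr_l <- synth_reach_trial(cfg_l, test_geom, 4)
  # mirrored: the left trial's LMCP2 is the right trial's RMCP2 with x flipped
  expect_equal(tr_l$markers$LMCP2[, 1], -tr_r$markers$RMCP2[, 1])
  expect_equal(tr_l$markers$LMCP2[, 2:3], tr_r$markers$RMCP2[, 2:3])
  p_r <- reach_parameters(tr_r, test_geom)
  p_l <- reach_parameters(tr_l, test_geom, endpoint_marker = "RMCP2")
  for (v in kin_param_names) {
    expect_equal(p_l[[v]], p_r[[v]], tolerance = 1e-9, label = v)
  }
})

test_that("invalid targets and unreachable panels raise typed errors", {
  expect_error(synth_reach_trial(clean_config(), test_geom, 0),
               class = "reachkin_error_invalid_argument")
  far <- panel_geometry(subject_distance = 70)  # beyond a 60 cm arm
  expect_error(synth_reach_trial(clean_config(), far, 12),
               class = "reachkin_error_infeasible_configuration")
})

test_that("tidy round trip preserves the analysis", {
  trial <- synth_reach_trial(clean_config(n_submovements = 2), test_geom, 8)
  df <- as_tibble(trial)
  expect_named(df, c("subject", "session", "arm", "side", "target", "frame",
                     "time_s", "marker", "x_cm", "y_cm", "z_cm"))
  back <- trial_from_tibble(df)
  p1 <- reach_parameters(trial, test_geom)
  p2 <- reach_parameters(back, test_geom)
  expect_equal(p2[kin_param_names], p1[kin_param_names], tolerance = 1e-9)
})
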