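# Forward-kinematic fixture: a static trunk with the right arm driven by
# prescribed shoulder projection angles and elbow flexion, built with the
# same chain convention the extractor uses.
fk_arm_trial <- function(fe_deg, aa_deg, elbow_deg, fs = 120,
                         d1 = 27, flen = 25) {
  n <- length(fe_deg)
  stopifnot(length(aa_deg) == n, length(elbow_deg) == n)
  const <- function(v) matrix(v, n, 3, byrow = TRUE)
  mid <- c(0, 0, 100)
  mk <- list(
    RSHO = const(mid + c(17.5, 0, 0)), LSHO = const(mid + c(-17.5, 0, 0)),
    CLAV = const(mid + c(0, 4, -3)), C7 = const(mid + c(0, -6, -2)),
    STRN = const(mid + c(0, 6, -18)), T10 = const(mid + c(0, -8, -20))
  )
  frame <- reachkin:::.thorax_frame(mk$C7, mk$CLAV, mk$T10, mk$STRN,
                                    mk$LSHO, mk$RSHO)
  u <- reachkin:::.fk_humerus_dir(fe_deg, aa_deg, frame)
  mk$RELB <- mk$RSHO + d1 * u
  # forearm direction: humerus rotated by the elbow angle toward the
  # thorax anterior axis
  w <- frame$y - rowSums(frame$y * u) * u
  w <- w / sqrt(rowSums(w^2))
  phi <- elbow_deg * pi / 180
  f <- cos(phi) * u + sin(phi) * w
  wri <- mk$RELB + flen * f
  m <- reachkin:::.cross3(f, frame$z)
  m <- m / sqrt(rowSums(m^2))
  mk$RRSP <- wri - 2 * m
  mk$RUSP <- wri + 2 * m
  mk$RMCP2 <- wri + 8 * f
  structure(
    list(subject_id = "FK", session = "pre", arm = "paretic",
         side = "right", target_index = 1L, sample_rate = fs,
         time = seq(0, by = 1 / fs, length.out = n), markers = mk,
         truth = NULL, config = NULL),
    class = "reach_trial"
  )
}

test_that("elbow angle is 0 for a straight arm and 90 for a right angle", {
  n <- 20
  tr0 <- fk_arm_trial(rep(40, n), rep(10, n), rep(0, n))
  expect_equal(max(abs(elbow_flexion_angle(tr0, cutoff = NULL)$angle_deg)), 0,
               tolerance = 1e-6)
  tr90 <- fk_arm_trial(rep(40, n), rep(10, n), rep(90, n))
  expect_equal(elbow_flexion_angle(tr90, cutoff = NULL)$angle_deg, rep(90, n),
               tolerance = 1e-6)
})

test_that("an arm hanging along the thorax vertical reads FE = AA = 0", {
  tr <- fk_arm_trial(rep(0, 20), rep(0, 20), rep(20, 20))
  sh <- shoulder_angles(tr, cutoff = NULL)
  expect_equal(max(abs(sh$fe_deg)), 0, tolerance = 1e-6)
  expect_equal(max(abs(sh$aa_deg)), 0, tolerance = 1e-6)
})

test_that("prescribed joint excursions are recovered exactly", {
  n <- 120
  ramp <- 0.5 - 0.5 * cos(seq(0, 2 * pi, length.out = n))  # 0 -> 1 -> 0
  # pure 30-degree flexion excursion
  tr_fe <- fk_arm_trial(30 * ramp, rep(0, n), rep(25, n))
  sh <- shoulder_angles(tr_fe, cutoff = NULL)
  expect_equal(angle_range(sh$fe_deg), 30, tolerance = 0.5)
  expect_lt(angle_range(sh$aa_deg), 1)
  # prescribed 40-degree elbow excursion
  tr_el <- fk_arm_trial(rep(20, n), rep(5, n), 20 + 40 * ramp)
  expect_equal(angle_range(elbow_flexion_angle(tr_el, cutoff = NULL)$angle_deg),
               40, tolerance = 0.5)
})

test_that("shoulder angles are thorax-relative: whole-body rotation leaves them fixed", {
  n <- 60
  tr <- fk_arm_trial(rep(25, n), rep(10, n), rep(35, n))
  ang <- seq(0, 15, length.out = n) * pi / 180
  rot <- tr
  rot$markers <- lapply(tr$markers, function(m) {
    cbind(m[, 1] * cos(ang) - m[, 2] * sin(ang),
          m[, 1] * sin(ang) + m[, 2] * cos(ang),
          m[, 3])
  })
  sh <- shoulder_angles(rot, cutoff = NULL)
  expect_lt(angle_range(sh$fe_deg), 1)
  expect_lt(angle_range(sh$aa_deg), 1)
  expect_lt(angle_range(elbow_flexion_angle(rot, cutoff = NULL)$angle_deg), 1)
  # ... while the thorax rotation series sees exactly the applied rotation
  th <- thorax_rotation(rot, cutoff = NULL)
  expect_equal(angle_range(th$rotation_deg), 15, tolerance = 0.01)
})

test_that("thorax rotation recovers the injected axial rotation and ignores translation", {
  trial <- synth_reach_trial(clean_config(trunk_rotation = 10), test_geom, 6)
  th <- thorax_rotation(trial, cutoff = NULL)
  expect_equal(angle_range(th$rotation_deg), 10, tolerance = 0.2)
  # rigid whole-body translation rotates nothing
  shifted <- trial
  shifted$markers <- lapply(trial$markers, function(m) {
    sweep(m, 2, c(25, -10, 5), "+")
  })
  expect_equal(angle_range(thorax_rotation(shifted, cutoff = NULL)$rotation_deg),
               angle_range(th$rotation_deg), tolerance = 1e-9)
})

test_that("torso excursion recovers the injected trunk lean", {
  static <- synth_reach_trial(clean_config(), test_geom, 12)
  expect_equal(torso_excursion(static, truth_segment(static), cutoff = NULL), 0,
               tolerance = 1e-9)
  lean <- synth_reach_trial(clean_config(trunk_translation = 5), test_geom, 12)
  expect_equal(torso_excursion(lean, cutoff = NULL), 5, tolerance = 0.1)
})

test_that("torso excursion stays within 0.2 cm of truth under marker noise", {
  errs <- vapply(1:100, function(i) {
    cfg <- sim_config(trunk_translation = 5, marker_noise_sd = 0.05,
                      seed = 900 + i)
    trial <- synth_reach_trial(cfg, test_geom, (i - 1) %% 12 + 1)
    torso_excursion(trial) - trial$truth$true_trunk_excursion
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.2)
})

test_that("round trip: simulator chain to extracted ranges across all targets", {
  for (i in 1:20) {
    cfg <- clean_config(n_submovements = (i - 1) %% 3 + 1,
                        movement_duration = 1 + (i %% 4) * 0.25,
                        path_curvature_gain = 0.15,
                        trunk_translation = 3, trunk_rotation = 4, seed = i)
    trial <- synth_reach_trial(cfg, test_geom, (i - 1) %% 12 + 1)
    sh <- shoulder_angles(trial, cutoff = NULL)
    el <- elbow_flexion_angle(trial, cutoff = NULL)
    expect_equal(angle_range(sh$fe_deg), trial$truth$true_ShFE, tolerance = 0.5)
    expect_equal(angle_range(sh$aa_deg), trial$truth$true_ShAA, tolerance = 0.5)
    expect_equal(angle_range(el$angle_deg), trial$truth$true_ElFE, tolerance = 0.5)
    expect_equal(torso_excursion(trial, cutoff = NULL),
                 trial$truth$true_trunk_excursion, tolerance = 0.1)
  }
})

test_that("missing frames are interpolated up to 10% and refused beyond", {
  trial <- synth_reach_trial(clean_config(), test_geom, 5)
  n <- length(trial$time)
  few <- trial
  bad <- seq(50, 50 + floor(0.05 * n))
  few$markers$RELB[bad, ] <- NA
  expect_silent(el <- elbow_flexion_angle(few, cutoff = NULL))
  expect_false(anyNA(el$angle_deg))
  many <- trial
  many$markers$RELB[seq(10, 10 + ceiling(0.15 * n)), ] <- NA
  expect_error(elbow_flexion_angle(many, cutoff = NULL),
               class = "reachkin_error_insufficient_markers")
  dropped <- trial
  dropped$markers$RELB <- NULL
  expect_error(shoulder_angles(dropped), class = "reachkin_error_schema")
})
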