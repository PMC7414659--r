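#' Simulation configuration for a synthetic reach trial
#'
#' Bundles the generative parameters of one synthetic reach-to-target
#' trial. The movement model is a composition of minimum-jerk submovements
#' along the start-to-target chord (out and back), optionally corrupted by
#' path curvature (an out-of-chord half-sine bump), compensatory trunk
#' translation and axial trunk rotation time-locked to the reach, and
#' i.i.d. Gaussian marker noise. Arm markers are placed by a two-link
#' inverse-kinematic chain, so true joint excursions are computable.
#'
#' @param arm_length Acromion-to-fist (closed) arm length, cm.
#' @param forearm_length Lateral epicondyle to ulnar styloid, cm.
#' @param hand_length Ulnar styloid to second metacarpal head (fist), cm.
#' @param shoulder_width Inter-acromion distance, cm.
#' @param movement_duration Duration of one phase (outbound reach) in s;
#'   the full out-and-back movement lasts twice this. Snapped to the frame
#'   grid.
#' @param n_submovements Number of minimum-jerk submovements per phase
#'   (>= 1); ignored when `submovement_schedule` is given.
#' @param submovement_schedule Optional schedule data frame (`onset`,
#'   `amplitude`, `duration` as fractions; see [compose_submovements()]).
#' @param path_curvature_gain Dimensionless >= 0; the lateral apex of the
#'   path bump equals this fraction of the chord length (0 = straight).
#' @param trunk_translation Peak compensatory trunk translation along the
#'   reach direction, cm >= 0.
#' @param trunk_rotation Peak axial trunk rotation, degrees >= 0.
#' @param marker_noise_sd Per-axis Gaussian marker noise SD, cm >= 0.
#' @param sample_rate Frames/s (default 120, typical optical capture).
#' @param side Which arm the trial uses, `"right"` or `"left"`; left
#'   trials are generated by mirroring about the sagittal plane.
#' @param rest_pad Still rest time prepended/appended to the movement, s.
#' @param seed Integer seed; trials are pure functions of
#'   (config, geometry, target).
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(arm_length = 60,
                       forearm_length = 25,
                       hand_length = 8,
                       shoulder_width = 35,
                       movement_duration = 1.25,
                       n_submovements = 1,
                       submovement_schedule = NULL,
                       path_curvature_gain = 0,
                       trunk_translation = 0,
                       trunk_rotation = 0,
                       marker_noise_sd = 0,
                       sample_rate = 120,
                       side = c("right", "left"),
                       rest_pad = 0.25,
                       seed = 1L) {
  side <- match.arg(side)
  .assert_scalar_num(arm_length, "arm_length", positive = TRUE)
  .assert_scalar_num(forearm_length, "forearm_length", positive = TRUE)
  .assert_scalar_num(hand_length, "hand_length", positive = TRUE)
  .assert_scalar_num(shoulder_width, "shoulder_width", positive = TRUE)
  .assert_scalar_num(movement_duration, "movement_duration", positive = TRUE)
  .assert_scalar_num(path_curvature_gain, "path_curvature_gain", nonneg = TRUE)
  .assert_scalar_num(trunk_translation, "trunk_translation", nonneg = TRUE)
  .assert_scalar_num(trunk_rotation, "trunk_rotation", nonneg = TRUE)
  .assert_scalar_num(marker_noise_sd, "marker_noise_sd", nonneg = TRUE)
  .assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  .assert_scalar_num(rest_pad, "rest_pad", nonneg = TRUE)
  if (forearm_length + hand_length >= arm_length) {
    abort("forearm_length + hand_length must be smaller than arm_length",
          class = "reachkin_error_invalid_argument")
  }
  if (is.null(submovement_schedule)) {
    submovement_schedule <- submovement_schedule(n_submovements)
  } else {
    submovement_schedule <- validate_schedule(submovement_schedule)
    n_submovements <- nrow(submovement_schedule)
  }
  # snap the phase duration to the frame grid so the outbound apex falls
  # exactly on a sampled frame
  movement_duration <- round(movement_duration * sample_rate) / sample_rate
  rest_pad <- round(rest_pad * sample_rate) / sample_rate
  structure(
    list(
      arm_length = arm_length, forearm_length = forearm_length,
      hand_length = hand_length, shoulder_width = shoulder_width,
      movement_duration = movement_duration,
      n_submovements = as.integer(n_submovements),
      submovement_schedule = submovement_schedule,
      path_curvature_gain = path_curvature_gain,
      trunk_translation = trunk_translation,
      trunk_rotation = trunk_rotation,
      marker_noise_sd = marker_noise_sd,
      sample_rate = sample_rate, side = side,
      rest_pad = rest_pad, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Unit-scale composed profile evaluated at arbitrary phase fractions.
.compose_eval <- function(schedule, tau) {
  pos <- numeric(length(tau))
  for (i in seq_len(nrow(schedule))) {
    ti <- pmin(pmax((tau - schedule$onset[i]) / schedule$duration[i], 0), 1)
    pos <- pos + schedule$amplitude[i] * .mj_pos(ti)
  }
  pos
}

# One-way generated path length (cm) for chord length L and curvature gain
# g: the path is chord + g*L*sin(pi*u) lateral bump, u = chord fraction.
.path_length_oneway <- function(L, g) {
  if (g == 0) return(L)
  L * stats::integrate(function(u) sqrt(1 + (g * pi * cos(pi * u))^2),
                       0, 1, rel.tol = 1e-10)$value
}

#' Simulate one reach-to-target trial with ground truth
#'
#' Generates a 20-marker upper-body recording of one out-and-back reach to
#' a panel target, together with the generating ground truth needed for
#' parameter-recovery testing. See [sim_config()] for the movement model.
#'
#' @param config A [sim_config()] object.
#' @param geometry A [panel_geometry()] object.
#' @param target_index Target number 1-12.
#' @param subject_id,session,arm Metadata attached to the recording.
#' @return An object of class `reach_trial`: a list with metadata, `time`
#'   (s), `markers` (named list of n x 3 matrices, cm), and `truth` (a
#'   one-row tibble with true movement time, path length, straight
#'   distance, velocity-peak count per phase, trunk excursion, thorax
#'   rotation range, and true joint ranges ShFE/ShAA/ElFE). Use
#'   [as_tibble()][tibble::as_tibble] for the long tidy form.
#' @examples
#' geom <- panel_geometry()
#' trial <- synth_reach_trial(sim_config(seed = 7), geom, target_index = 3)
#' trial$truth
#' @export
synth_reach_trial <- function(config, geometry, target_index,
                              subject_id = "S01",
                              session = c("pre", "post"),
                              arm = c("paretic", "nonparetic")) {
  stopifnot(inherits(config, "sim_config"), inherits(geometry, "panel_geometry"))
  session <- match.arg(session)
  arm <- match.arg(arm)
  tgt <- target_position(geometry, target_index)

  fs <- config$sample_rate
  Tph <- config$movement_duration
  pad <- config$rest_pad
  total <- 2 * Tph + 2 * pad
  n <- as.integer(round(total * fs)) + 1L
  time <- seq(0, by = 1 / fs, length.out = n)

  # movement progress u(t) in [0, 1]: 0 at rest, 1 at the outbound apex;
  # the return phase replays the submovement schedule time-reversed.
  # Frame indices avoid floating-point phase misclassification.
  u <- numeric(n)
  sched <- config$submovement_schedule
  i0 <- as.integer(round(pad * fs)) + 1L          # movement onset frame
  ia <- i0 + as.integer(round(Tph * fs))          # outbound apex frame
  i1 <- ia + as.integer(round(Tph * fs))          # movement end frame
  out_idx <- i0:ia
  ret_idx <- if (i1 > ia) (ia + 1L):i1 else integer(0)
  u[out_idx] <- .compose_eval(sched, (out_idx - i0) / (ia - i0))
  u[ret_idx] <- .compose_eval(sched, 1 - (ret_idx - ia) / (i1 - ia))

  start <- geometry$start_position
  chord <- tgt - start
  L <- .norm3(chord)
  chat <- chord / L
  # lateral bump direction: horizontal, perpendicular to the chord
  lat <- c(chat[2], -chat[1], 0)
  if (.norm3(lat) < 1e-9) lat <- c(1, 0, 0) else lat <- lat / .norm3(lat)
  g <- config$path_curvature_gain
  endpoint <- matrix(start, n, 3, byrow = TRUE) +
    outer(u, chord) + outer(g * L * sin(pi * u), lat)

  # trunk pose: translation along the reach direction plus axial rotation
  # about the vertical through the mid-acromion point, both time-locked to u
  sho_r_rest <- geometry$shoulder_position
  w <- config$shoulder_width
  mid_rest <- sho_r_rest - c(w / 2, 0, 0)
  trunk_rel <- list(
    RSHO = c(w / 2, 0, 0), LSHO = c(-w / 2, 0, 0),
    CLAV = c(0, 4, -3), C7 = c(0, -6, -2),
    STRN = c(0, 6, -18), T10 = c(0, -8, -20)
  )
  d1 <- config$arm_length - config$forearm_length - config$hand_length
  d2 <- config$forearm_length + config$hand_length
  # non-tested (left) arm hangs at the side, rigid with the trunk
  trunk_rel$LELB <- trunk_rel$LSHO + c(0, 0, -d1)
  lwri <- trunk_rel$LELB + c(0, 0, -config$forearm_length)
  trunk_rel$LRSP <- lwri + c(-2, 0, 0)
  trunk_rel$LUSP <- lwri + c(2, 0, 0)
  trunk_rel$LMCP1 <- lwri + c(-1.5, 2, -config$hand_length)
  trunk_rel$LMCP2 <- lwri + c(1.5, 2, -config$hand_length)
  trunk_rel$LUPA <- trunk_rel$LSHO + c(-3, 0, -d1 * 0.55)
  trunk_rel$LFRA <- trunk_rel$LELB + c(-3, 0, -config$forearm_length * 0.5)

  shift <- outer(u * config$trunk_translation, chat)
  theta <- config$trunk_rotation * u * pi / 180
  ct <- cos(theta); st <- sin(theta)
  place_trunk <- function(rel) {
    rx <- rel[1] ; ry <- rel[2]; rz <- rel[3]
    cbind(mid_rest[1] + shift[, 1] + rx * ct - ry * st,
          mid_rest[2] + shift[, 2] + rx * st + ry * ct,
          mid_rest[3] + shift[, 3] + rz)
  }
  markers <- lapply(trunk_rel, place_trunk)

  # tested (right) arm by inverse kinematics from the moving shoulder
  sho <- markers$RSHO
  elb <- .ik_elbow(sho, endpoint, d1, d2)
  distal_dir <- .unit_rows(endpoint - elb)
  wri <- elb + config$forearm_length * distal_dir
  mhat <- .cross3(distal_dir,
                  matrix(rep(c(0, 0, 1), each = n), ncol = 3))
  mn <- .rownorm(mhat)
  degen <- mn < 1e-9
  if (any(degen)) {
    mhat[degen, ] <- matrix(rep(c(1, 0, 0), each = sum(degen)), ncol = 3)
    mn[degen] <- 1
  }
  mhat <- mhat / mn
  markers$RELB <- elb
  markers$RUPA <- sho + 0.55 * (elb - sho) + 3 * mhat
  markers$RFRA <- elb + 0.5 * (wri - elb) + 2.5 * mhat
  markers$RRSP <- wri - 2 * mhat
  markers$RUSP <- wri + 2 * mhat
  markers$RMCP1 <- elb + (d2 - 3) / d2 * (endpoint - elb) - 1.5 * mhat
  markers$RMCP2 <- endpoint

  truth <- .trial_truth(config, markers, L, g, Tph)

  if (config$side == "left") markers <- .mirror_markers(markers)

  if (config$marker_noise_sd > 0) {
    trial_seed <- .derive_seed(config$seed, target_index,
                               match(session, c("pre", "post")),
                               match(arm, c("paretic", "nonparetic")))
    markers <- .with_seed(trial_seed, {
      lapply(markers, function(m) {
        m + matrix(rnorm(length(m), sd = config$marker_noise_sd), nrow(m), 3)
      })
    })
  }

  structure(
    list(
      subject_id = subject_id, session = session, arm = arm,
      side = config$side, target_index = as.integer(target_index),
      sample_rate = fs, time = time, markers = markers,
      truth = truth, config = config
    ),
    class = "reach_trial"
  )
}

# Ground truth from the noiseless generating chain (right-side canonical).
.trial_truth <- function(config, markers, L, g, Tph) {
  frame <- .thorax_frame(markers$C7, markers$CLAV, markers$T10,
                         markers$STRN, markers$LSHO, markers$RSHO)
  u_local <- .in_frame(.unit_rows(markers$RELB - markers$RSHO), frame)
  sh <- .shoulder_fe_aa(u_local)
  wri <- (markers$RRSP + markers$RUSP) / 2
  el <- .elbow_angle(markers$RSHO, markers$RELB, wri)
  rng <- function(x) diff(range(x, na.rm = TRUE))
  # trunk excursion from the generating CLAV path: equals the injected
  # translation when rotation is zero, and their (non-additive)
  # combination otherwise
  clav <- markers$CLAV
  texc <- max(.rownorm(clav - matrix(clav[1L, ], nrow(clav), 3, byrow = TRUE)))
  tibble::tibble(
    true_MT = 2 * Tph,
    true_path_length = .path_length_oneway(L, g),
    true_straight_distance = L,
    true_n_velocity_peaks = config$n_submovements,
    true_trunk_excursion = texc,
    true_thorax_rotation_range = config$trunk_rotation,
    true_ShFE = rng(sh$fe),
    true_ShAA = rng(sh$aa),
    true_ElFE = rng(el)
  )
}

# Mirror a right-arm scene about the sagittal plane and swap side labels.
.mirror_markers <- function(markers) {
  flipped <- lapply(markers, function(m) { m[, 1] <- -m[, 1]; m })
  nm <- names(flipped)
  swapped <- ifelse(startsWith(nm, "R"), sub("^R", "L", nm),
                    ifelse(startsWith(nm, "L"), sub("^L", "R", nm), nm))
  names(flipped) <- swapped
  flipped
}

#' @export
print.reach_trial <- function(x, ...) {
  cat("<reach_trial>", x$subject_id, x$session, x$arm,
      sprintf("target %d", x$target_index), "\n")
  cat(sprintf("  %d frames at %g frames/s, %d markers\n",
              length(x$time), x$sample_rate, length(x$markers)))
  invisible(x)
}

#' Long tidy form of a recorded trial
#'
#' @param x A `reach_trial`.
#' @param ... Unused.
#' @return A tibble with columns `subject`, `session`, `arm`, `side`,
#'   `target`, `frame`, `time_s`, `marker`, `x_cm`, `y_cm`, `z_cm`.
#' @export
as_tibble.reach_trial <- function(x, ...) {
  nmark <- length(x$markers)
  n <- length(x$time)
  tibble::tibble(
    subject = x$subject_id,
    session = x$session,
    arm = x$arm,
    side = x$side,
    target = x$target_index,
    frame = rep(seq_len(n), nmark),
    time_s = rep(x$time, nmark),
    marker = rep(names(x$markers), each = n),
    x_cm = unlist(lapply(x$markers, function(m) m[, 1]), use.names = FALSE),
    y_cm = unlist(lapply(x$markers, function(m) m[, 2]), use.names = FALSE),
    z_cm = unlist(lapply(x$markers, function(m) m[, 3]), use.names = FALSE)
  )
}
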