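#' Names of the eleven kinematic parameters
#'
#' Column order used by [reach_parameters()] and the aggregate tables:
#' movement time (MT, s), trajectory directness (CurvI), peak velocity
#' (Vmax, cm/s), time to peak velocity (TpctVmax, % of movement duration),
#' number of velocity peaks (NVP), log dimensionless jerk (LDJ), ranges of
#' shoulder flexion/extension (ShFE), shoulder abduction/adduction (ShAA)
#' and elbow flexion/extension (ElFE) in degrees, thorax rotation range
#' (Th, degrees) and torso excursion (TExc, cm).
#'
#' @export
kin_param_names <- c("MT", "CurvI", "Vmax", "TpctVmax", "NVP", "LDJ",
                     "ShFE", "ShAA", "ElFE", "Th", "TExc")

#' Extract the eleven kinematic parameters from one trial
#'
#' Runs the full per-trial chain: zero-phase low-pass filtering of the
#' marker trajectories, endpoint speed computation, velocity-threshold
#' segmentation, then the six endpoint parameters (MT, CurvI, Vmax,
#' TpctVmax, NVP, LDJ) and the five joint/trunk parameters (ShFE, ShAA,
#' ElFE, Th, TExc) over the analyzed segment.
#'
#' @param trial A `reach_trial` object or a long-format marker tibble as
#'   produced by [as_tibble.reach_trial()] / [read_markers_csv()].
#' @param geometry Optional [panel_geometry()]; when given, the outbound
#'   movement end is additionally gated on target capture.
#' @param cutoff Low-pass cutoff, Hz.
#' @param threshold_fraction Segmentation threshold as a fraction of peak
#'   speed.
#' @param phase Analysis phase: `"full_cycle"` (start to target and back;
#'   default) or `"outbound"`.
#' @param min_prominence_fraction,min_separation_s Velocity-peak counting
#'   settings, see [count_velocity_peaks()].
#' @param endpoint_marker Endpoint marker label after canonicalisation to
#'   the right arm (default `"RMCP2"`, the second metacarpal head).
#' @return A one-row tibble: `subject`, `session`, `arm`, `target`,
#'   `phase`, `onset_frame`, `end_frame`, then the eleven parameters in
#'   the order of [kin_param_names].
#' @examples
#' geom <- panel_geometry()
#' trial <- synth_reach_trial(sim_config(seed = 2), geom, 12)
#' reach_parameters(trial, geom)
#' @export
reach_parameters <- function(trial,
                             geometry = NULL,
                             cutoff = 6,
                             threshold_fraction = 0.05,
                             phase = c("full_cycle", "outbound"),
                             min_prominence_fraction = 0.05,
                             min_separation_s = 0.1,
                             endpoint_marker = "RMCP2") {
  phase <- match.arg(phase)
  if (is.data.frame(trial)) trial <- trial_from_tibble(trial)
  stopifnot(inherits(trial, "reach_trial"))
  fs <- trial$sample_rate

  mk <- .canonical_markers(trial, cutoff,
                           needed = unique(c("C7", "CLAV", "T10", "STRN",
                                             "LSHO", "RSHO", "RELB",
                                             "RRSP", "RUSP", endpoint_marker)))
  endpoint <- mk[[endpoint_marker]]
  speed <- speed_profile(endpoint, fs)

  target <- NULL
  if (!is.null(geometry)) {
    target <- target_position(geometry, trial$target_index)
    if (identical(trial$side, "left")) target[1] <- -target[1]
  }
  segment <- detect_reach_bounds(speed, threshold_fraction, phase,
                                 positions = endpoint, target = target)
  rows <- segment$onset_frame:segment$end_frame
  sp <- speed[rows]
  ep <- endpoint[rows, , drop = FALSE]

  frame <- .thorax_frame(mk$C7, mk$CLAV, mk$T10, mk$STRN, mk$LSHO, mk$RSHO)
  sh <- .shoulder_fe_aa(.in_frame(.unit_rows(mk$RELB - mk$RSHO), frame))
  wri <- (mk$RRSP + mk$RUSP) / 2
  elfe <- .elbow_angle(mk$RSHO, mk$RELB, wri)
  th <- .acromion_rotation(mk$LSHO[rows, , drop = FALSE],
                           mk$RSHO[rows, , drop = FALSE])
  clav <- mk$CLAV[rows, , drop = FALSE]

  tibble::tibble(
    subject = trial$subject_id,
    session = trial$session,
    arm = trial$arm,
    target = trial$target_index,
    phase = phase,
    onset_frame = segment$onset_frame,
    end_frame = segment$end_frame,
    MT = movement_time(segment, fs),
    CurvI = trajectory_directness(ep, phase),
    Vmax = peak_velocity(sp),
    TpctVmax = time_to_peak_pct(sp),
    NVP = count_velocity_peaks(sp, fs, min_prominence_fraction,
                               min_separation_s),
    LDJ = log_dimensionless_jerk(sp, fs),
    ShFE = angle_range(sh$fe[rows]),
    ShAA = angle_range(sh$aa[rows]),
    ElFE = angle_range(elfe[rows]),
    Th = angle_range(th),
    TExc = max(.rownorm(clav - matrix(clav[1L, ], nrow(clav), 3,
                                      byrow = TRUE)))
  )
}

#' Rebuild a trial object from its long tidy form
#'
#' Inverse of [as_tibble.reach_trial()]: validates the frame grid and
#' marker set and returns a `reach_trial` usable by the extraction
#' functions.
#'
#' @param df Long-format tibble with columns `subject`, `session`, `arm`,
#'   `side`, `target`, `frame`, `time_s`, `marker`, `x_cm`, `y_cm`,
#'   `z_cm` (one trial only).
#' @return A `reach_trial`.
#' @export
trial_from_tibble <- function(df) {
  need <- c("subject", "session", "arm", "target", "frame", "time_s",
            "marker", "x_cm", "y_cm", "z_cm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("marker table lacks columns: ",
                 paste(missing, collapse = ", ")),
          class = "reachkin_error_schema")
  }
  if (!"side" %in% names(df)) df$side <- "right"
  if (nrow(dplyr::distinct(df[, c("subject", "session", "arm", "target")])) != 1L) {
    abort("expected exactly one trial per table",
          class = "reachkin_error_schema")
  }
  if (anyDuplicated(df[, c("marker", "frame")])) {
    abort("duplicated frame index within a marker trajectory",
          class = "reachkin_error_parse")
  }
  df <- dplyr::arrange(df, .data$marker, .data$frame)
  frames <- sort(unique(df$frame))
  times <- df$time_s[match(frames, df$frame)]
  dt <- diff(times)
  if (any(dt <= 0) || (length(dt) > 1 && diff(range(dt)) > 1e-6)) {
    abort("frame times must increase at a constant sampling interval",
          class = "reachkin_error_parse")
  }
  fs <- round(1 / stats::median(dt))
  markers <- lapply(split(df, df$marker), function(d) {
    if (nrow(d) != length(frames)) {
      abort("markers cover different frame ranges",
            class = "reachkin_error_parse")
    }
    unname(as.matrix(d[, c("x_cm", "y_cm", "z_cm")]))
  })
  structure(
    list(
      subject_id = df$subject[1L], session = df$session[1L],
      arm = df$arm[1L], side = df$side[1L],
      target_index = as.integer(df$target[1L]),
      sample_rate = fs, time = times, markers = markers,
      truth = NULL, config = NULL
    ),
    class = "reach_trial"
  )
}

#' Aggregate per-movement parameters to subject-session level
#'
#' Averages the eleven kinematic parameters over all movements of each
#' subject x session x arm cell (the per-session battery of reaches), the
#' unit entering the correlation and group-change analyses. The mean is
#' the default; the median is available.
#'
#' @param params Per-movement parameter table from [reach_parameters()]
#'   rows bound together.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return A tibble with `subject`, `session`, `arm`, `n_movements` and
#'   the eleven parameter columns.
#' @export
aggregate_parameters <- function(params, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  fn <- if (statistic == "mean") mean else median
  present <- intersect(kin_param_names, names(params))
  params |>
    dplyr::group_by(.data$subject, .data$session, .data$arm) |>
    dplyr::summarise(
      n_movements = dplyr::n(),
      dplyr::across(dplyr::all_of(present), ~ fn(.x)),
      .groups = "drop"
    )
}
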