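# Joint-range and trunk-movement parameters from marker positions.
#
# Angles use an explicit, reproducible thorax-frame convention (see
# kinchain.R) rather than a proprietary biomechanical model: the shoulder
# is decomposed as two projection angles of the humerus in the thorax
# frame (a universal-joint reading, no axial humeral rotation), the elbow
# as the angle between upper-arm and forearm vectors, trunk rotation as
# the transverse-plane rotation of the inter-acromion line relative to
# movement onset, and torso excursion as the peak displacement of the
# suprasternal-notch (CLAV) marker from its onset position.

# Canonical right-arm marker matrices for a trial, gap-filled and
# optionally low-pass filtered. Left-side trials are mirrored about the
# sagittal plane first so sign conventions match the right arm.
.canonical_markers <- function(trial, cutoff = 6,
                               needed = c("C7", "CLAV", "T10", "STRN",
                                          "LSHO", "RSHO", "RELB",
                                          "RRSP", "RUSP", "RMCP2")) {
  stopifnot(inherits(trial, "reach_trial"))
  markers <- trial$markers
  if (identical(trial$side, "left")) markers <- .mirror_markers(markers)
  missing <- setdiff(needed, names(markers))
  if (length(missing)) {
    abort(paste0("missing marker labels: ", paste(missing, collapse = ", ")),
          class = "reachkin_error_schema")
  }
  out <- lapply(markers[needed], .fill_gaps)
  if (!is.null(cutoff)) {
    out <- lapply(out, lowpass_filter, cutoff = cutoff,
                  sample_rate = trial$sample_rate)
  }
  out
}

# Linear interpolation of missing frames, up to 10% of the series;
# more than that aborts (the recording is considered unreconstructed).
.fill_gaps <- function(m) {
  bad <- !complete.cases(m)
  if (!any(bad)) return(m)
  if (mean(bad) > 0.10) {
    abort("more than 10% of frames missing for a required marker",
          class = "reachkin_error_insufficient_markers")
  }
  idx <- seq_len(nrow(m))
  for (j in 1:3) {
    ok <- !is.na(m[, j])
    m[, j] <- approx(idx[ok], m[ok, j], xout = idx, rule = 2)$y
  }
  m
}

.segment_rows <- function(trial, segment) {
  if (is.null(segment)) return(seq_along(trial$time))
  stopifnot(inherits(segment, "reach_segment"))
  segment$onset_frame:segment$end_frame
}

#' Elbow flexion/extension angle
#'
#' Per-frame angle between the upper-arm vector (acromion to lateral
#' epicondyle) and the forearm vector (lateral epicondyle to the midpoint
#' of the radial and ulnar styloid markers); 0 degrees is full extension.
#'
#' @param trial A `reach_trial` (simulated or read from file).
#' @param segment Optional `reach_segment` restricting the frames.
#' @param cutoff Low-pass cutoff in Hz applied to marker trajectories
#'   before the angle computation (`NULL` to skip filtering).
#' @return A tibble with `frame`, `time_s`, `angle_deg`.
#' @seealso [angle_range()]
#' @export
elbow_flexion_angle <- function(trial, segment = NULL, cutoff = 6) {
  mk <- .canonical_markers(trial, cutoff,
                           needed = c("RSHO", "RELB", "RRSP", "RUSP"))
  rows <- .segment_rows(trial, segment)
  wri <- (mk$RRSP + mk$RUSP) / 2
  ang <- .elbow_angle(mk$RSHO, mk$RELB, wri)[rows]
  tibble::tibble(frame = rows, time_s = trial$time[rows], angle_deg = ang)
}

#' Shoulder flexion/extension and abduction/adduction angles
#'
#' The humerus direction (acromion to lateral epicondyle) is expressed in
#' the thorax anatomical frame; flexion/extension is the angle of its
#' sagittal-plane projection and abduction/adduction of its frontal-plane
#' projection, both 0 for an arm hanging along the thorax vertical.
#' Frames in which a projection degenerates (humerus along the
#' decomposition axis) are returned as `NA` with a warning.
#'
#' @inheritParams elbow_flexion_angle
#' @return A tibble with `frame`, `time_s`, `fe_deg`, `aa_deg`.
#' @export
shoulder_angles <- function(trial, segment = NULL, cutoff = 6) {
  mk <- .canonical_markers(trial, cutoff,
                           needed = c("C7", "CLAV", "T10", "STRN",
                                      "LSHO", "RSHO", "RELB"))
  rows <- .segment_rows(trial, segment)
  frame <- .thorax_frame(mk$C7, mk$CLAV, mk$T10, mk$STRN, mk$LSHO, mk$RSHO)
  u <- .in_frame(.unit_rows(mk$RELB - mk$RSHO), frame)
  sh <- .shoulder_fe_aa(u)
  fe <- sh$fe[rows]
  aa <- sh$aa[rows]
  if (anyNA(fe) || anyNA(aa)) {
    warn("gimbal-adjacent frames flagged NA and excluded from ranges")
  }
  tibble::tibble(frame = rows, time_s = trial$time[rows],
                 fe_deg = fe, aa_deg = aa)
}

#' Thorax axial rotation
#'
#' Transverse-plane angle between the inter-acromion line at each frame
#' and its orientation at the segment onset (0 at onset by construction).
#'
#' @inheritParams elbow_flexion_angle
#' @return A tibble with `frame`, `time_s`, `rotation_deg`.
#' @export
thorax_rotation <- function(trial, segment = NULL, cutoff = 6) {
  mk <- .canonical_markers(trial, cutoff, needed = c("LSHO", "RSHO"))
  rows <- .segment_rows(trial, segment)
  rot <- .acromion_rotation(mk$LSHO[rows, , drop = FALSE],
                            mk$RSHO[rows, , drop = FALSE])
  tibble::tibble(frame = rows, time_s = trial$time[rows], rotation_deg = rot)
}

#' Torso excursion
#'
#' Maximum displacement of the suprasternal-notch (CLAV) marker from its
#' position at segment onset, in cm: the scalar summary of compensatory
#' trunk movement during the reach.
#'
#' @inheritParams elbow_flexion_angle
#' @return Length-1 numeric, cm.
#' @export
torso_excursion <- function(trial, segment = NULL, cutoff = 6) {
  mk <- .canonical_markers(trial, cutoff, needed = "CLAV")
  rows <- .segment_rows(trial, segment)
  clav <- mk$CLAV[rows, , drop = FALSE]
  max(.rownorm(clav - matrix(clav[1L, ], nrow(clav), 3, byrow = TRUE)))
}

#' Range of an angle series
#'
#' Max minus min over the analyzed segment, ignoring flagged (`NA`)
#' frames. Applies to the elbow, shoulder and thorax angle series.
#'
#' @param x Numeric vector of angles in degrees, or a tibble produced by
#'   one of the angle functions (its last column is used).
#' @return Range in degrees (>= 0).
#' @export
angle_range <- function(x) {
  if (is.data.frame(x)) x <- x[[ncol(x)]]
  x <- x[!is.na(x)]
  if (!length(x)) {
    abort("no valid frames to compute a range over",
          class = "reachkin_error_insufficient_data")
  }
  diff(range(x))
}
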