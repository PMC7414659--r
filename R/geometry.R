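#' Reach-to-target panel geometry
#'
#' Describes the vertical target panel used in the reach-to-target protocol:
#' twelve numbered targets arranged clockwise like a clock face, 20 cm from
#' the panel center, with the center aligned with the acromion of the tested
#' arm and the panel placed at fist-closed arm distance from the subject. A
#' start target sits at forearm distance from the panel center along the
#' line joining the center and the shoulder.
#'
#' Coordinates are right-handed with +Z vertical, +Y anterior (subject
#' toward panel) and +X to the subject's right, in cm. Target 12 is at the
#' top of the clock; target 3 on the subject's right.
#'
#' @param arm_length Acromion-to-fist arm length in cm; sets the default
#'   subject-to-panel distance.
#' @param forearm_length Lateral epicondyle to ulnar styloid length in cm;
#'   sets the start-target distance from the panel center.
#' @param radius Radius of the target circle in cm (default 20).
#' @param subject_distance Distance from the shoulder to the panel plane in
#'   cm. The default, `sqrt(arm_length^2 - radius^2) - 1`, keeps every
#'   target reachable by the arm alone with a 1 cm margin.
#' @param shoulder_position 3D position of the tested-arm acromion at rest.
#' @return An object of class `panel_geometry`: a list with the panel
#'   `center`, `radius`, `start_position`, `subject_distance`,
#'   `shoulder_position` and a `targets` tibble (columns `target`, `x`,
#'   `y`, `z`).
#' @examples
#' geom <- panel_geometry()
#' geom$targets
#' @export
panel_geometry <- function(arm_length = 60,
                           forearm_length = 25,
                           radius = 20,
                           subject_distance = NULL,
                           shoulder_position = c(17.5, 0, 100)) {
  .assert_scalar_num(arm_length, "arm_length", positive = TRUE)
  .assert_scalar_num(forearm_length, "forearm_length", positive = TRUE)
  .assert_scalar_num(radius, "radius", positive = TRUE)
  if (radius >= arm_length) {
    abort("target radius must be smaller than arm length",
          class = "reachkin_error_infeasible_configuration")
  }
  if (is.null(subject_distance)) {
    subject_distance <- sqrt(arm_length^2 - radius^2) - 1
  }
  .assert_scalar_num(subject_distance, "subject_distance", positive = TRUE)
  stopifnot(length(shoulder_position) == 3, all(is.finite(shoulder_position)))

  center <- shoulder_position + c(0, subject_distance, 0)
  # clock layout in the panel (x-z) plane, clockwise from 12 o'clock at top
  idx <- 1:12
  phi <- pi / 2 - idx * pi / 6
  targets <- tibble::tibble(
    target = idx,
    x = center[1] + radius * cos(phi),
    y = center[2],
    z = center[3] + radius * sin(phi)
  )
  start <- center + forearm_length * .unit(shoulder_position - center)
  structure(
    list(
      center = center,
      radius = radius,
      start_position = start,
      subject_distance = subject_distance,
      shoulder_position = shoulder_position,
      arm_length = arm_length,
      forearm_length = forearm_length,
      targets = targets
    ),
    class = "panel_geometry"
  )
}

#' @export
print.panel_geometry <- function(x, ...) {
  cat("<panel_geometry>\n")
  cat(sprintf("  12 targets, radius %.1f cm, panel at y = %.1f cm\n",
              x$radius, x$center[2]))
  cat(sprintf("  start target at (%.1f, %.1f, %.1f) cm\n",
              x$start_position[1], x$start_position[2], x$start_position[3]))
  invisible(x)
}

#' Target position lookup
#'
#' @param geometry A [panel_geometry()] object.
#' @param target_index Target number, 1-12.
#' @return Numeric length-3 position in cm.
#' @export
target_position <- function(geometry, target_index) {
  stopifnot(inherits(geometry, "panel_geometry"))
  if (!is.numeric(target_index) || length(target_index) != 1L ||
      !(target_index %in% 1:12)) {
    abort("`target_index` must be an integer between 1 and 12",
          class = "reachkin_error_invalid_argument")
  }
  unlist(geometry$targets[geometry$targets$target == target_index,
                          c("x", "y", "z")], use.names = FALSE)
}
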