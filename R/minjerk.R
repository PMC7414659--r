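#' Minimum-jerk point-to-point trajectory
#'
#' Samples the quintic minimum-jerk trajectory
#' \eqn{x(\tau) = A\,(10\tau^3 - 15\tau^4 + 6\tau^5)}, \eqn{\tau = t/T},
#' the canonical smooth model of an unimpaired point-to-point reach. Its
#' speed profile is bell-shaped and symmetric, peaking at mid-movement with
#' value \eqn{1.875\,A/T}.
#'
#' @param amplitude Movement amplitude \eqn{A} in cm (> 0).
#' @param duration Movement duration \eqn{T} in s (> 0).
#' @param sample_rate Sampling rate in frames/s; `sample_rate * duration`
#'   must give at least 10 samples.
#' @return A tibble with columns `time` (s), `position` (cm) and `speed`
#'   (cm/s, the analytic derivative). Position runs from 0 to `amplitude`;
#'   speed is zero at both ends.
#' @examples
#' mj <- min_jerk_profile(30, 1, 120)
#' max(mj$speed) # ~ 1.875 * 30 / 1
#' @export
min_jerk_profile <- function(amplitude, duration, sample_rate) {
  .assert_scalar_num(amplitude, "amplitude", positive = TRUE)
  .assert_scalar_num(duration, "duration", positive = TRUE)
  .assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  n <- floor(duration * sample_rate) + 1L
  if (n < 10L) {
    abort("sample_rate * duration must give at least 10 samples",
          class = "reachkin_error_invalid_argument")
  }
  t <- seq(0, by = 1 / sample_rate, length.out = n)
  tau <- pmin(t / duration, 1)
  tibble::tibble(
    time = t,
    position = amplitude * .mj_pos(tau),
    speed = amplitude / duration * .mj_vel(tau)
  )
}

# Unit-amplitude, unit-duration minimum-jerk position and its derivative.
.mj_pos <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
.mj_vel <- function(tau) 30 * tau^2 * (1 - tau)^2

#' Compose time-shifted minimum-jerk submovements
#'
#' Builds a 1D displacement profile as a sum of time-shifted minimum-jerk
#' components. Impaired reaches decompose into such submovements; composing
#' them with little temporal overlap produces a speed profile with exactly
#' one local maximum per submovement, which makes the generated trials
#' usable as ground truth for velocity-peak counting.
#'
#' @param schedule A data frame with columns `onset`, `amplitude`,
#'   `duration`, all as fractions of the whole movement: onsets and
#'   durations relative to `duration`, amplitudes summing to 1. See
#'   [submovement_schedule()] for a canonical layout.
#' @param amplitude Total displacement in cm (> 0).
#' @param duration Total duration in s (> 0).
#' @param sample_rate Frames/s.
#' @return A tibble with `time`, `position` and `speed` (analytic sum of
#'   component speeds). Final position equals `amplitude`.
#' @seealso [min_jerk_profile()]
#' @export
compose_submovements <- function(schedule, amplitude, duration, sample_rate) {
  schedule <- validate_schedule(schedule)
  .assert_scalar_num(amplitude, "amplitude", positive = TRUE)
  .assert_scalar_num(duration, "duration", positive = TRUE)
  .assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  n <- floor(duration * sample_rate) + 1L
  t <- seq(0, by = 1 / sample_rate, length.out = n)
  pos <- numeric(n)
  vel <- numeric(n)
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset[i] * duration
    du <- schedule$duration[i] * duration
    am <- schedule$amplitude[i] * amplitude
    tau <- pmin(pmax((t - on) / du, 0), 1)
    pos <- pos + am * .mj_pos(tau)
    vel <- vel + am / du * .mj_vel(tau)
  }
  tibble::tibble(time = t, position = pos, speed = vel)
}

#' Canonical disjoint submovement schedule
#'
#' Lays out `k` equal-amplitude minimum-jerk submovements back to back with
#' a small gap between consecutive components, so that the composed speed
#' profile has exactly `k` local maxima.
#'
#' @param k Number of submovements (integer >= 1).
#' @param gap Fraction of each slot left empty between components
#'   (default 0.1, i.e. each submovement occupies 90% of its slot).
#' @return A schedule tibble accepted by [compose_submovements()].
#' @export
submovement_schedule <- function(k, gap = 0.1) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer", class = "reachkin_error_invalid_argument")
  }
  if (gap < 0 || gap >= 1) {
    abort("`gap` must lie in [0, 1)", class = "reachkin_error_invalid_argument")
  }
  slot <- 1 / k
  tibble::tibble(
    onset = (seq_len(k) - 1L) * slot,
    amplitude = rep(1 / k, k),
    duration = rep(slot * (1 - gap), k)
  )
}

# Validates the SimConfig schedule invariants: amplitudes sum to 1, every
# component fits inside the unit window.
validate_schedule <- function(schedule) {
  schedule <- tibble::as_tibble(schedule)
  need <- c("onset", "amplitude", "duration")
  if (!all(need %in% names(schedule))) {
    abort("schedule needs columns onset, amplitude, duration",
          class = "reachkin_error_invalid_argument")
  }
  if (nrow(schedule) < 1L) {
    abort("schedule must contain at least one submovement",
          class = "reachkin_error_invalid_argument")
  }
  if (any(schedule$duration <= 0) || any(schedule$onset < 0)) {
    abort("submovement onsets must be >= 0 and durations > 0",
          class = "reachkin_error_invalid_argument")
  }
  if (any(schedule$onset + schedule$duration > 1 + 1e-9)) {
    abort("submovements must end inside the movement window",
          class = "reachkin_error_invalid_argument")
  }
  if (abs(sum(schedule$amplitude) - 1) > 1e-9) {
    abort("submovement amplitude fractions must sum to 1",
          class = "reachkin_error_invalid_argument")
  }
  schedule
}
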