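#' Movement time of a segmented reach
#'
#' Time elapsed between movement onset and end.
#'
#' @param segment A `reach_segment` from [detect_reach_bounds()].
#' @param sample_rate Frames/s.
#' @return Movement time in seconds.
#' @export
movement_time <- function(segment, sample_rate) {
  stopifnot(inherits(segment, "reach_segment"))
  .assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  (segment$end_frame - segment$onset_frame) / sample_rate
}

#' Trajectory directness (curvature index)
#'
#' Ratio of the traversed path length to the straight-line distance between
#' the movement's first and last positions; 1 means a perfectly straight
#' reach. For a full out-and-back cycle the two endpoints coincide, so the
#' index is computed per half-cycle (split at the apex, the point most
#' distant from the start) and averaged.
#'
#' @param positions n x 3 matrix (or data frame) of endpoint positions
#'   within the analyzed segment, cm.
#' @param phase `"outbound"` for a one-way movement, `"full_cycle"` for an
#'   out-and-back movement.
#' @return Dimensionless ratio, >= 1 for noiseless data.
#' @export
trajectory_directness <- function(positions, phase = c("outbound", "full_cycle")) {
  phase <- match.arg(phase)
  pos <- as.matrix(positions)
  if (nrow(pos) < 2L) {
    abort("need at least 2 frames", class = "reachkin_error_insufficient_data")
  }
  if (phase == "outbound") {
    return(.directness_oneway(pos))
  }
  d <- .rownorm(pos - matrix(pos[1L, ], nrow(pos), 3, byrow = TRUE))
  apex <- which.max(d)
  if (apex < 2L || apex > nrow(pos) - 1L) {
    abort("cannot split a full cycle at the apex",
          class = "reachkin_error_degenerate_trial")
  }
  (.directness_oneway(pos[1:apex, , drop = FALSE]) +
      .directness_oneway(pos[apex:nrow(pos), , drop = FALSE])) / 2
}

.directness_oneway <- function(pos) {
  chord <- .norm3(pos[nrow(pos), ] - pos[1L, ])
  if (chord < 1e-9) {
    abort("movement endpoints coincide; directness undefined",
          class = "reachkin_error_degenerate_trial")
  }
  arc <- sum(.rownorm(diff(pos)))
  arc / chord
}

#' Peak velocity and its timing
#'
#' `peak_velocity()` returns the global maximum of the speed series within
#' the segment; `time_to_peak_pct()` returns the time from movement onset
#' to that maximum as a percentage of the movement duration. Ties are
#' broken to the earliest frame.
#'
#' @param speed Speed series (cm/s) restricted to the analyzed segment.
#' @return `peak_velocity()`: cm/s. `time_to_peak_pct()`: percentage in
#'   (0, 100).
#' @export
peak_velocity <- function(speed) {
  if (!length(speed)) {
    abort("empty speed series", class = "reachkin_error_insufficient_data")
  }
  max(speed)
}

#' @rdname peak_velocity
#' @export
time_to_peak_pct <- function(speed) {
  if (length(speed) < 2L) {
    abort("need at least 2 frames", class = "reachkin_error_insufficient_data")
  }
  100 * (which.max(speed) - 1L) / (length(speed) - 1L)
}

#' Number of velocity peaks
#'
#' Counts local maxima of the speed profile whose topographic prominence is
#' at least `min_prominence_fraction` of the segment's peak speed and that
#' are separated by at least `min_separation_s`. A fragmented (less smooth)
#' movement produces more velocity peaks. The defaults (5% prominence,
#' 0.1 s separation) are reported alongside results.
#'
#' @param speed Speed series within the segment, cm/s.
#' @param sample_rate Frames/s.
#' @param min_prominence_fraction Minimum peak prominence as a fraction of
#'   peak speed.
#' @param min_separation_s Minimum time between counted peaks, s.
#' @return Integer count, >= 1 whenever the segment contains movement.
#' @export
count_velocity_peaks <- function(speed, sample_rate,
                                 min_prominence_fraction = 0.05,
                                 min_separation_s = 0.1) {
  .assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  if (!length(speed) || max(speed) <= 0) {
    abort("speed profile contains no movement",
          class = "reachkin_error_no_movement")
  }
  pk <- .peak_prominences(speed)
  keep <- pk$prominence >= min_prominence_fraction * max(speed)
  idx <- pk$index[keep]
  hgt <- pk$height[keep]
  if (!length(idx)) return(1L) # single smooth burst: its maximum is the peak
  # greedy enforcement of the minimum separation, tallest peaks first
  ord <- order(hgt, decreasing = TRUE)
  min_gap <- min_separation_s * sample_rate
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(idx[i] - accepted) >= min_gap)) {
      accepted <- c(accepted, idx[i])
    }
  }
  length(accepted)
}

# Local maxima of a series with their topographic prominence: height above
# the higher of the two lowest valleys separating the peak from higher
# terrain (or the series boundary).
.peak_prominences <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(index = integer(0), height = numeric(0),
                          prominence = numeric(0)))
  core <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  prom <- vapply(core, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(x[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    right <- x[(i + 1L):n]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  list(index = core, height = x[core], prominence = prom)
}

#' Log dimensionless jerk
#'
#' Movement smoothness as the negative natural logarithm of the
#' dimensionless squared-jerk integral
#' \deqn{LDJ = -\ln\!\left(\frac{MT^3}{V_{max}^2}\int_0^{MT} j(t)^2\,dt\right),}
#' where \eqn{j} is the second time-derivative of the (filtered) endpoint
#' speed, i.e. the jerk along the path. The duration-cubed, peak-speed-
#' squared normalization makes the metric invariant to spatial and temporal
#' rescaling; smoother movements give values closer to zero (a noiseless
#' minimum-jerk reach gives \eqn{-\ln(204.8) \approx -5.32}), fragmented
#' movements more negative values.
#'
#' @param speed Speed series within the segment, cm/s (filtered upstream).
#' @param sample_rate Frames/s.
#' @return Dimensionless, strictly negative.
#' @export
log_dimensionless_jerk <- function(speed, sample_rate) {
  .assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  if (length(speed) < 7L) {
    abort("segment too short for third-order differentiation",
          class = "reachkin_error_insufficient_data")
  }
  vmax <- max(speed)
  if (vmax <= 0) {
    abort("speed profile contains no movement",
          class = "reachkin_error_no_movement")
  }
  mt <- (length(speed) - 1L) / sample_rate
  jerk <- .gradient(.gradient(speed, sample_rate), sample_rate)
  integral <- pracma::trapz(seq_along(speed) / sample_rate, jerk^2)
  -log(mt^3 / vmax^2 * integral)
}
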