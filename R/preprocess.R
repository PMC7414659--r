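#' Zero-phase low-pass filter for marker trajectories
#'
#' Fourth-order zero-phase Butterworth low-pass (a second-order filter run
#' forward and backward), the standard conditioning step before numerical
#' differentiation of optical marker data. The input is reflected (odd
#' extension) at both ends before filtering to suppress edge transients.
#'
#' @param series Numeric vector, or matrix with one signal per column.
#' @param cutoff Cutoff frequency in Hz; must lie in (0, sample_rate / 2).
#' @param sample_rate Sampling rate in Hz.
#' @return Filtered series, same shape as the input. A constant input is
#'   returned unchanged (to within 1e-9).
#' @export
lowpass_filter <- function(series, cutoff, sample_rate) {
  .assert_scalar_num(cutoff, "cutoff", positive = TRUE)
  .assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  if (cutoff >= sample_rate / 2) {
    abort("cutoff must be below the Nyquist frequency",
          class = "reachkin_error_invalid_argument")
  }
  if (is.matrix(series)) {
    return(apply(series, 2L, lowpass_filter,
                 cutoff = cutoff, sample_rate = sample_rate))
  }
  n <- length(series)
  if (n < 4L) return(series)
  co <- .butter_coefs(cutoff, sample_rate)
  # Even (mirror) reflection: appropriate for series that start and end
  # at rest, and it lets the filter average out boundary noise (an odd
  # reflection would pin the endpoint and leave its noise unsmoothed).
  npad <- min(n - 1L, as.integer(ceiling(3 * sample_rate / cutoff)))
  front <- series[(npad + 1L):2L]
  back <- series[(n - 1L):(n - npad)]
  # filter about the mean: a constant passes through exactly and start-up
  # transients of the zero-initial-condition passes shrink
  m <- mean(series)
  x <- c(front, series, back) - m
  y <- .iir_pass(co$b, co$a, x)
  y <- rev(.iir_pass(co$b, co$a, rev(y)))
  y[(npad + 1L):(npad + n)] + m
}

# Second-order Butterworth design, memoized per (cutoff, rate).
.butter_env <- new.env(parent = emptyenv())
.butter_coefs <- function(cutoff, sample_rate) {
  key <- paste(cutoff, sample_rate)
  co <- .butter_env[[key]]
  if (is.null(co)) {
    bf <- signal::butter(2, cutoff / (sample_rate / 2), type = "low")
    co <- list(b = bf$b / bf$a[1], a = bf$a / bf$a[1])
    .butter_env[[key]] <- co
  }
  co
}

# Single causal IIR pass with zero initial conditions, via the compiled
# convolution and recursive filters (edge transients are absorbed by the
# reflection padding added in lowpass_filter).
.iir_pass <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(numeric(nb - 1L), x), b, sides = 1)
  v <- v[nb:(nb - 1L + length(x))]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Endpoint speed profile
#'
#' Speed of a marker as the norm of the central-difference derivative of
#' its position (one-sided differences at the ends). This series is the
#' basis of the peak-velocity, velocity-peak-count and smoothness metrics.
#'
#' @param positions An n x 3 matrix (or data frame) of positions in cm, or
#'   a numeric vector for 1D motion.
#' @param sample_rate Frames/s.
#' @return Non-negative numeric vector of speeds, cm/s.
#' @export
speed_profile <- function(positions, sample_rate) {
  .assert_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  if (is.data.frame(positions)) positions <- as.matrix(positions)
  if (is.matrix(positions)) {
    if (nrow(positions) < 3L) {
      abort("need at least 3 frames to estimate speed",
            class = "reachkin_error_insufficient_data")
    }
    return(.rownorm(.gradient(positions, sample_rate)))
  }
  if (length(positions) < 3L) {
    abort("need at least 3 frames to estimate speed",
          class = "reachkin_error_insufficient_data")
  }
  abs(.gradient(positions, sample_rate))
}

#' Segment a trial into an analyzed movement
#'
#' Detects movement onset and end from the endpoint speed profile with a
#' relative velocity threshold, replacing manual event marking with a
#' documented automatic rule. Onset is the last frame before the outbound
#' speed peak at which speed drops below `threshold_fraction` times that
#' peak. For `phase = "outbound"` the end is the symmetric event after the
#' outbound peak (optionally gated on the endpoint being within
#' `capture_radius` of the target); for `phase = "full_cycle"` it is the
#' symmetric event after the return-phase speed peak.
#'
#' @param speed Non-negative speed series, cm/s.
#' @param threshold_fraction Relative threshold in (0, 1); default 0.05
#'   (5% of peak speed).
#' @param phase `"full_cycle"` (out and back; default) or `"outbound"`.
#' @param positions Optional n x 3 endpoint positions; used to locate the
#'   outbound apex (most distant point from the start) and to gate the
#'   outbound end on target capture.
#' @param target Optional length-3 target position (cm).
#' @param capture_radius Radius (cm) around the target within which the
#'   outbound movement may be declared finished; used only when both
#'   `positions` and `target` are given.
#' @return A `reach_segment`: list with `onset_frame`, `end_frame`,
#'   `phase` (frame indices into the supplied series, onset < end).
#' @export
detect_reach_bounds <- function(speed,
                                threshold_fraction = 0.05,
                                phase = c("full_cycle", "outbound"),
                                positions = NULL,
                                target = NULL,
                                capture_radius = 2) {
  phase <- match.arg(phase)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1)",
          class = "reachkin_error_invalid_argument")
  }
  n <- length(speed)
  vmax <- max(speed)
  if (!is.finite(vmax) || vmax <= 0) {
    abort("speed profile contains no movement",
          class = "reachkin_error_no_movement")
  }

  # For an outbound-only analysis the outbound peak is the global speed
  # maximum (restricted to before the apex when positions are available);
  # the apex dip is only needed to separate the phases of a full cycle.
  apex <- if (phase == "outbound" && is.null(positions)) {
    n
  } else {
    .find_apex(speed, positions, threshold_fraction)
  }

  # Onset: last sub-threshold frame before the first crossing of the
  # outbound threshold (for a single-peaked reach this is the last frame
  # below threshold before the outbound peak). Using the first/last
  # crossing rather than the dip adjacent to the tallest peak keeps every
  # submovement of a fragmented reach inside the segment.
  thr_out <- threshold_fraction * max(speed[seq_len(apex)])
  first_up <- which(speed >= thr_out)[1L]
  if (is.na(first_up)) {
    abort("speed never crosses the outbound threshold",
          class = "reachkin_error_degenerate_trial")
  }
  onset <- max(first_up - 1L, 1L)

  if (phase == "outbound") {
    peak <- which.max(speed[seq_len(apex)])
    thr <- threshold_fraction * speed[peak]
    end <- .first_below_after(speed, peak, thr)
    if (!is.null(positions) && !is.null(target)) {
      pos <- as.matrix(positions)
      near <- .rownorm(pos - matrix(target, n, 3, byrow = TRUE)) <=
        capture_radius
      cand <- which(seq_len(n) > peak & speed < thr & near)
      if (length(cand)) end <- cand[1L]
    }
  } else {
    # End: first sub-threshold frame after the last crossing of the
    # return-phase threshold (the symmetric event after the return peak).
    thr_ret <- threshold_fraction * max(speed[apex:n])
    up_ret <- which(seq_len(n) >= apex & speed >= thr_ret)
    last_up <- up_ret[length(up_ret)]
    if (last_up >= n) {
      abort("movement still above threshold at the last frame",
            class = "reachkin_error_degenerate_trial")
    }
    end <- last_up + 1L
  }
  if (onset >= end) {
    abort("degenerate trial: could not bracket a movement",
          class = "reachkin_error_degenerate_trial")
  }
  structure(list(onset_frame = onset, end_frame = end, phase = phase),
            class = "reach_segment")
}

# Outbound apex: most distant point from the start position when positions
# are available; otherwise the speed minimum between the first and last
# crossing of the relative threshold (the mid-movement dip of an
# out-and-back trial).
.find_apex <- function(speed, positions, threshold_fraction) {
  n <- length(speed)
  if (!is.null(positions)) {
    pos <- as.matrix(positions)
    d <- .rownorm(pos - matrix(pos[1L, ], n, 3, byrow = TRUE))
    return(which.max(d))
  }
  thr <- threshold_fraction * max(speed)
  above <- which(speed >= thr)
  lo <- above[1L]
  hi <- above[length(above)]
  if (hi - lo < 2L) return(which.max(speed))
  mid <- lo:hi
  mid[which.min(speed[mid])]
}

.first_below_after <- function(speed, peak, thr) {
  n <- length(speed)
  if (peak >= n) {
    abort("speed peak at the last frame; cannot find movement end",
          class = "reachkin_error_degenerate_trial")
  }
  below <- which(speed[(peak + 1L):n] < thr)
  if (!length(below)) {
    abort("speed never drops below threshold after the peak",
          class = "reachkin_error_degenerate_trial")
  }
  peak + below[1L]
}

#' @export
print.reach_segment <- function(x, ...) {
  cat(sprintf("<reach_segment> frames %d..%d (%s)\n",
              x$onset_frame, x$end_frame, x$phase))
  invisible(x)
}
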