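# Shared fixtures: one default panel and a few canonical configurations.

test_geom <- panel_geometry()

# A clean single-submovement reach (no curvature, no trunk motion, no
# noise): the simplest trial every extraction stage must handle exactly.
clean_config <- function(...) {
  args <- utils::modifyList(
    list(path_curvature_gain = 0, trunk_translation = 0,
         trunk_rotation = 0, marker_noise_sd = 0, seed = 1),
    list(...)
  )
  do.call(sim_config, args)
}

# Segment covering the generating movement window of a simulated trial.
truth_segment <- function(trial) {
  fs <- trial$sample_rate
  i0 <- round(trial$config$rest_pad * fs) + 1L
  structure(list(onset_frame = i0,
                 end_frame = i0 + round(trial$truth$true_MT * fs),
                 phase = "full_cycle"),
            class = "reach_segment")
}

# Independent peak-count oracle: sign changes of the first difference
# (strict rise followed by fall), ignoring sub-tolerance wiggles.
count_peaks_oracle <- function(speed, tol = 1e-9) {
  d <- diff(speed)
  d[abs(d) < tol] <- 0
  s <- sign(d)
  s <- s[s != 0]
  sum(head(s, -1) == 1 & tail(s, -1) == -1)
}
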