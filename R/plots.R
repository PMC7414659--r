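# ggplot2 views of trials and result tables.

#' Endpoint speed profile with detected movement bounds
#'
#' @param trial A `reach_trial` (object or long tibble).
#' @param cutoff,threshold_fraction,phase As in [reach_parameters()].
#' @return A ggplot.
#' @export
plot_speed_profile <- function(trial, cutoff = 6, threshold_fraction = 0.05,
                               phase = c("full_cycle", "outbound")) {
  phase <- match.arg(phase)
  if (is.data.frame(trial)) trial <- trial_from_tibble(trial)
  mk <- .canonical_markers(trial, cutoff, needed = "RMCP2")
  speed <- speed_profile(mk$RMCP2, trial$sample_rate)
  seg <- detect_reach_bounds(speed, threshold_fraction, phase,
                             positions = mk$RMCP2)
  df <- tibble::tibble(time = trial$time, speed = speed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = trial$time[c(seg$onset_frame, seg$end_frame)],
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(x = "time (s)", y = "endpoint speed (cm/s)",
                  title = sprintf("%s %s target %d", trial$subject_id,
                                  trial$session, trial$target_index)) +
    ggplot2::theme_minimal()
}

#' Correlation grid heat map
#'
#' Tile plot of a [correlation_grid()] result: Spearman rho per kinematic
#' parameter x clinical measure, annotated with Holm-adjusted
#' significance.
#'
#' @param grid Output of [correlation_grid()].
#' @param alpha Significance level for the annotation.
#' @return A ggplot.
#' @export
plot_correlation_grid <- function(grid, alpha = 0.05) {
  grid$cell <- paste(grid$measure, grid$variant)
  grid$sig <- ifelse(grid$p_holm < alpha, "*", "")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$parameter, y = .data$cell,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$rho, .data$sig)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r_s",
                  title = unique(grid$scope)) +
    ggplot2::theme_minimal()
}

#' Subject-by-subject effect sizes
#'
#' Dot plot of the baseline-standardized effect size of each subject's
#' pre-to-post kinematic change (improvement positive), filled by
#' Holm-adjusted significance.
#'
#' @param subject_table Output of [subject_change_table()].
#' @return A ggplot.
#' @export
plot_subject_effects <- function(subject_table) {
  subject_table$status <- ifelse(subject_table$significant,
                                 "significant", "n.s.")
  ggplot2::ggplot(subject_table,
                  ggplot2::aes(x = .data$subject, y = .data$d,
                               fill = .data$status)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(shape = 21, size = 2.5) +
    ggplot2::facet_wrap(~ .data$variable, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(significant = "black",
                                          n.s. = "white")) +
    ggplot2::labs(x = NULL, y = "Cohen's d (improvement positive)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
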