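# Synthetic study cohorts. A latent impairment scalar per subject drives
# both the kinematic generators (submovement count, movement slowness,
# path curvature, trunk compensation) and, through a Gaussian copula, the
# clinical outcome scores, so that every downstream statistic has a known
# generative target.

# Map a latent impairment value (N(0,1) scale, higher = more impaired) to
# the per-session generative settings of one arm.
.impairment_settings <- function(zeta, arm) {
  if (arm == "nonparetic") {
    return(list(k = 1L, duration = 1.0, curvature = 0.03,
                trunk_translation = 2, trunk_rotation = 1.5))
  }
  list(
    k = as.integer(pmin(4, pmax(1, round(2.5 + zeta)))),
    duration = pmin(2.0, pmax(0.8, 1.2 + 0.25 * zeta)),
    curvature = pmin(0.70, pmax(0.05, 0.35 + 0.15 * zeta)),
    trunk_translation = pmin(20, pmax(0, 8 + 4 * zeta)),
    trunk_rotation = pmin(15, pmax(0, 5 + 2.5 * zeta))
  )
}

#' Simulate a reach-to-target study cohort
#'
#' Generates per-movement kinematic parameter tables for a cohort of
#' subjects measured pre- and post-intervention with both arms, mirroring
#' the reach-to-target study design (12 clock targets per session; the
#' study protocol uses 3 repetitions for 36 movements per arm). Each
#' subject carries a latent impairment value that sets submovement count,
#' movement duration, path curvature and trunk compensation for the
#' paretic arm; the non-paretic arm uses mildly-variable unimpaired
#' settings. `improvement` shifts the post-session latent impairment
#' (0 = no true kinematic change, the null cohort used for calibration
#' testing).
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; the cohort is a pure function of its
#'   arguments.
#' @param targets Target indices per session (default all 12).
#' @param reps Repetitions per target (default 3, giving the study's 36
#'   movements per arm and session; reduce for quick experiments).
#' @param arms Arms to simulate.
#' @param improvement Pre-to-post reduction of latent impairment, in SD
#'   units (0 = null cohort).
#' @param marker_noise_sd Marker noise SD, cm.
#' @param geometry A [panel_geometry()].
#' @param phase Analysis phase passed to [reach_parameters()].
#' @return A list with `params` (per-movement parameter tibble with
#'   `subject`, `session`, `arm`, `target`, `rep` and the eleven
#'   parameters), `truth` (matching generative ground truth rows) and
#'   `latent` (per-subject latent impairment).
#' @examples
#' \donttest{
#' cohort <- sim_cohort(n_subjects = 2, targets = c(3, 9), seed = 1)
#' aggregate_parameters(cohort$params)
#' }
#' @export
sim_cohort <- function(n_subjects = 10, seed = 1, targets = 1:12, reps = 3,
                       arms = c("paretic", "nonparetic"),
                       improvement = 0, marker_noise_sd = 0.05,
                       geometry = panel_geometry(),
                       phase = c("full_cycle", "outbound")) {
  phase <- match.arg(phase)
  arms <- match.arg(arms, several.ok = TRUE)
  subjects <- sprintf("S%02d", seq_len(n_subjects))

  plan <- .with_seed(.derive_seed(seed, 1), {
    z <- rnorm(n_subjects)
    grid <- tidyr::expand_grid(
      si = seq_len(n_subjects),
      session = c("pre", "post"),
      arm = arms,
      target = targets,
      rep = seq_len(reps)
    )
    jit <- function(n, lo, hi) runif(n, lo, hi)
    n <- nrow(grid)
    grid$dur_jit <- jit(n, 0.9, 1.1)
    grid$curv_jit <- jit(n, 0.8, 1.2)
    grid$tt_jit <- jit(n, 0.85, 1.15)
    grid$tr_jit <- jit(n, 0.85, 1.15)
    grid$k_jit <- rnorm(n, 0, 0.5)
    list(z = z, grid = grid)
  })

  rows <- purrr::pmap(plan$grid, function(si, session, arm, target, rep,
                                          dur_jit, curv_jit, tt_jit, tr_jit,
                                          k_jit) {
    zeta <- plan$z[si] - if (session == "post") improvement else 0
    st <- .impairment_settings(zeta, arm)
    # trial-to-trial variability in movement fragmentation
    k <- if (arm == "paretic") {
      as.integer(pmin(4, pmax(1, round(2.5 + zeta + k_jit))))
    } else st$k
    cfg <- sim_config(
      movement_duration = st$duration * dur_jit,
      n_submovements = k,
      path_curvature_gain = st$curvature * curv_jit,
      trunk_translation = st$trunk_translation * tt_jit,
      trunk_rotation = st$trunk_rotation * tr_jit,
      marker_noise_sd = marker_noise_sd,
      seed = .derive_seed(seed, si, match(session, c("pre", "post")),
                          match(arm, c("paretic", "nonparetic")),
                          target, rep)
    )
    trial <- synth_reach_trial(cfg, geometry, target,
                               subject_id = subjects[si],
                               session = session, arm = arm)
    p <- reach_parameters(trial, geometry, phase = phase)
    p$rep <- rep
    list(params = p, truth = dplyr::bind_cols(
      tibble::tibble(subject = subjects[si], session = session,
                     arm = arm, target = target, rep = rep),
      trial$truth
    ))
  })

  list(
    params = dplyr::bind_rows(purrr::map(rows, "params")),
    truth = dplyr::bind_rows(purrr::map(rows, "truth")),
    latent = tibble::tibble(subject = subjects, z = plan$z)
  )
}

#' Simulate clinical outcome scores for a cohort
#'
#' Generates pre/post clinical scores (FMA-UE, WMFT-FAS, WMFT-Time,
#' MAL-AOU, MAL-QOM, plus proximal variants of the first three) from the
#' cohort's latent impairment: each measure observes the session's latent
#' impairment through measure-specific noise, on its own scale and in its
#' own direction (WMFT-Time grows with impairment, all others shrink).
#'
#' @param latent Tibble with `subject` and `z` (from [sim_cohort()]).
#' @param improvement Pre-to-post latent impairment reduction in SD units
#'   applied to the clinical generators (may differ from the kinematic
#'   one to emulate dissociated recovery).
#' @param reliability Correlation between a measure's observation and the
#'   latent impairment (default 0.85).
#' @param seed Integer seed.
#' @return Clinical-scores tibble accepted by [correlation_grid()] and
#'   [mcid_flags()].
#' @export
sim_clinical_scores <- function(latent, improvement = 0,
                                reliability = 0.85, seed = 1) {
  stopifnot(all(c("subject", "z") %in% names(latent)))
  rel <- reliability
  .with_seed(.derive_seed(seed, 2), {
    grid <- tidyr::expand_grid(subject = latent$subject,
                               session = c("pre", "post"))
    grid$zeta <- latent$z[match(grid$subject, latent$subject)] -
      ifelse(grid$session == "post", improvement, 0)
    obs <- function() rel * grid$zeta + sqrt(1 - rel^2) * rnorm(nrow(grid))
    clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    fma <- clip(35.5 - 7 * obs(), 0, 66)
    fas <- clip(2.6 - 0.6 * obs(), 0, 5)
    wt <- exp(2.9 + 0.55 * obs())
    tibble::tibble(
      subject = grid$subject, session = grid$session,
      FMA_UE = fma,
      WMFT_FAS = fas,
      WMFT_Time = wt,
      MAL_AOU = clip(1.6 - 0.7 * obs(), 0, 5),
      MAL_QOM = clip(1.6 - 0.65 * obs(), 0, 5),
      FMA_UE_prox = clip(0.55 * fma + 1.5 * rnorm(nrow(grid)), 0, 36),
      WMFT_FAS_prox = clip(0.9 * fas + 0.2 * rnorm(nrow(grid)), 0, 5),
      WMFT_Time_prox = exp(log(wt) * 0.95 + 0.1 * rnorm(nrow(grid)))
    )
  })
}

#' Clinical scores linked to a kinematic aggregate by rank correlation
#'
#' Generates one clinical measure as a noisy monotone function of a
#' chosen kinematic aggregate through a Gaussian copula calibrated so
#' that the expected Spearman correlation between the two equals
#' `target_rs`: the aggregate's normal scores are mixed with independent
#' noise at copula correlation \eqn{\rho = 2\sin(\pi r_s / 6)}. Used as
#' the generative oracle for correlation-recovery testing.
#'
#' @param kin Aggregate kinematic table (paretic rows used), e.g. from
#'   [aggregate_parameters()].
#' @param parameter Kinematic column to link (default `"LDJ"`).
#' @param measure Clinical measure to generate (default `"FMA_UE"`).
#' @param target_rs Target Spearman correlation between parameter and
#'   measure across the pooled observations.
#' @param seed Integer seed.
#' @param center,scale Location and scale mapping the latent normal score
#'   to the measure's units.
#' @return Clinical-scores tibble with `subject`, `session` and the
#'   generated measure.
#' @export
sim_linked_clinical <- function(kin, parameter = "LDJ", measure = "FMA_UE",
                                target_rs = 0.7, seed = 1,
                                center = 35.5, scale = 7) {
  if ("arm" %in% names(kin)) kin <- dplyr::filter(kin, .data$arm == "paretic")
  x <- kin[[parameter]]
  n <- length(x)
  rho <- 2 * sin(pi * target_rs / 6)
  .with_seed(.derive_seed(seed, 3), {
    zx <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
    latent <- rho * zx + sqrt(1 - rho^2) * rnorm(n)
    out <- tibble::tibble(subject = kin$subject, session = kin$session)
    out[[measure]] <- center + scale * latent
    out
  })
}
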