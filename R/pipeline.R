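#' Pipeline configuration
#'
#' Assembles and validates the settings of one end-to-end analysis run.
#' Exactly one data source must be active: either `markers_csv` +
#' `clinical_csv` (recorded data) or `simulation` (a list of arguments
#' for [sim_cohort()], plus optional `clinical_improvement` and
#' `reliability` for [sim_clinical_scores()]).
#'
#' @param markers_csv,clinical_csv Input paths (recorded-data mode).
#' @param simulation Simulation block (simulated mode).
#' @param cutoff Low-pass cutoff, Hz.
#' @param threshold_fraction Segmentation threshold fraction.
#' @param phase Analysis phase, `"full_cycle"` or `"outbound"`.
#' @param min_prominence_fraction,min_separation_s Velocity-peak counting
#'   settings.
#' @param aggregate_statistic `"mean"` or `"median"`.
#' @param B Bootstrap resamples.
#' @param seed Integer seed for all stochastic steps.
#' @param holm_family Holm family policy for the correlation grids.
#' @param mcid MCID table, see [default_mcid_table()].
#' @param out_dir Optional output directory for the CSV report bundle.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(markers_csv = NULL, clinical_csv = NULL,
                            simulation = NULL,
                            cutoff = 6, threshold_fraction = 0.05,
                            phase = c("full_cycle", "outbound"),
                            min_prominence_fraction = 0.05,
                            min_separation_s = 0.1,
                            aggregate_statistic = c("mean", "median"),
                            B = 1000, seed = 1L,
                            holm_family = c("scope", "variant", "none"),
                            mcid = default_mcid_table(),
                            out_dir = NULL) {
  phase <- match.arg(phase)
  aggregate_statistic <- match.arg(aggregate_statistic)
  holm_family <- match.arg(holm_family)
  from_files <- !is.null(markers_csv)
  from_sim <- !is.null(simulation)
  if (from_files == from_sim) {
    abort("exactly one of {markers_csv, simulation} must be given",
          class = "reachkin_error_invalid_argument")
  }
  .assert_scalar_num(cutoff, "cutoff", positive = TRUE)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1)",
          class = "reachkin_error_invalid_argument")
  }
  structure(
    list(markers_csv = markers_csv, clinical_csv = clinical_csv,
         simulation = simulation, cutoff = cutoff,
         threshold_fraction = threshold_fraction, phase = phase,
         min_prominence_fraction = min_prominence_fraction,
         min_separation_s = min_separation_s,
         aggregate_statistic = aggregate_statistic,
         B = B, seed = as.integer(seed), holm_family = holm_family,
         mcid = mcid, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full reach-to-target analysis pipeline
#'
#' Orchestrates simulate/read, per-trial parameter extraction,
#' subject-session aggregation, correlation grids (cross-sectional and
#' longitudinal), group and subject-by-subject bootstrapped change
#' tables, non-paretic reference bands and MCID responder summary.
#' Identical configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle: named list of tibbles (`params`,
#'   `aggregates`, `correlations_cross`, `correlations_longitudinal`,
#'   `group_clinical`, `group_kinematic`, `subject_kinematic`,
#'   `mcid_flags`, `responders`, `provenance`). When `out_dir` is set,
#'   each table is also written as CSV.
#' @export
run_reach_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    clin_improve <- sim_args$clinical_improvement %||% 0
    reliability <- sim_args$reliability %||% 0.85
    sim_args$clinical_improvement <- NULL
    sim_args$reliability <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim_args$phase <- config$phase
    cohort <- do.call(sim_cohort, sim_args)
    params <- cohort$params
    clinical <- sim_clinical_scores(cohort$latent,
                                    improvement = clin_improve,
                                    reliability = reliability,
                                    seed = sim_args$seed)
  } else {
    markers <- read_markers_csv(config$markers_csv)
    params <- purrr::map(split_trials(markers), function(tr) {
      reach_parameters(tr,
                       cutoff = config$cutoff,
                       threshold_fraction = config$threshold_fraction,
                       phase = config$phase,
                       min_prominence_fraction = config$min_prominence_fraction,
                       min_separation_s = config$min_separation_s)
    }) |> dplyr::bind_rows()
    if ("rep" %in% names(markers)) params$rep <- 1L
    clinical <- if (!is.null(config$clinical_csv)) {
      read_clinical_csv(config$clinical_csv)
    } else NULL
  }

  aggregates <- aggregate_parameters(params, config$aggregate_statistic)

  cor_cross <- cor_long <- NULL
  group_clin <- flags <- responders <- NULL
  if (!is.null(clinical)) {
    cor_cross <- correlation_grid(aggregates, clinical,
                                  scope = "cross_sectional",
                                  holm_family = config$holm_family)
    cor_long <- correlation_grid(aggregates, clinical,
                                 scope = "longitudinal",
                                 holm_family = config$holm_family)
    clin_vars <- intersect(.clinical_meta$measure, names(clinical))
    dirs <- setNames(.clinical_meta$direction, .clinical_meta$measure)
    group_clin <- group_change_table(clinical, vars = clin_vars,
                                     directions = dirs, B = config$B,
                                     seed = .derive_seed(config$seed, 11))
    flags <- mcid_flags(clinical, config$mcid)
    responders <- responder_summary(flags)
  }

  group_kin <- group_change_table(aggregates, directions = kin_directions,
                                  B = config$B,
                                  seed = .derive_seed(config$seed, 12))

  reference <- NULL
  if ("arm" %in% names(aggregates) && any(aggregates$arm == "nonparetic")) {
    reference <- dplyr::filter(aggregates, .data$arm == "nonparetic")
  }
  subject_kin <- subject_change_table(params, reference = reference,
                                      B = config$B,
                                      seed = .derive_seed(config$seed, 13))

  provenance <- tibble::tibble(
    key = c("package_version", "config_hash", "seed", "phase", "cutoff_hz",
            "threshold_fraction", "aggregate_statistic", "bootstrap_B",
            "holm_family"),
    value = c(as.character(utils::packageVersion("reachkin")),
              rlang::hash(config), as.character(config$seed), config$phase,
              as.character(config$cutoff),
              as.character(config$threshold_fraction),
              config$aggregate_statistic, as.character(config$B),
              config$holm_family)
  )

  bundle <- list(
    params = params, aggregates = aggregates,
    correlations_cross = cor_cross,
    correlations_longitudinal = cor_long,
    group_clinical = group_clin, group_kinematic = group_kin,
    subject_kinematic = subject_kin,
    mcid_flags = flags, responders = responders,
    provenance = provenance
  )
  bundle <- bundle[!vapply(bundle, is.null, logical(1))]

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bundle)) {
      write.csv(bundle[[nm]], file.path(config$out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  invisible(bundle)
}
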