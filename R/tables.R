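# Study-level tables: correlation grids, group and subject-level change
# tables, MCID responder flags.

# Clinical outcome measures handled by the battery. WMFT-Time improves by
# decreasing; everything else by increasing. The first three also exist as
# proximal (shoulder/elbow items only) variants.
.clinical_meta <- tibble::tibble(
  measure = c("FMA_UE", "WMFT_FAS", "WMFT_Time", "MAL_AOU", "MAL_QOM"),
  direction = c("increase", "increase", "decrease", "increase", "increase"),
  has_proximal = c(TRUE, TRUE, TRUE, FALSE, FALSE)
)

#' Improvement direction of each kinematic parameter
#'
#' Direction in which a change counts as an improvement, used to
#' sign-adjust effect sizes: smaller movement time, directness index,
#' velocity-peak count, thorax rotation and torso excursion are better;
#' larger peak velocity, time-to-peak percentage, smoothness (LDJ toward
#' zero) and joint ranges are better.
#'
#' @export
kin_directions <- c(
  MT = "decrease", CurvI = "decrease", Vmax = "increase",
  TpctVmax = "increase", NVP = "decrease", LDJ = "increase",
  ShFE = "increase", ShAA = "increase", ElFE = "increase",
  Th = "decrease", TExc = "decrease"
)

#' Correlation grid between kinematic parameters and clinical outcomes
#'
#' Spearman rank correlations between subject-session kinematic aggregates
#' and clinical outcome measures, in the layout of a correlation table:
#' one cell per kinematic parameter x clinical measure x score variant
#' (total or proximal). The cross-sectional scope pools the pre- and
#' post-intervention observations (two rows per subject); the longitudinal
#' scope correlates per-subject post-minus-pre changes. Holm adjustment is
#' applied across the chosen family and each cell is labeled with the
#' Hinkle rule of thumb.
#'
#' @param kin Aggregate kinematic table from [aggregate_parameters()]
#'   (paretic-arm rows are used).
#' @param clinical Clinical-scores table: `subject`, `session`, measure
#'   columns (`FMA_UE`, `WMFT_FAS`, `WMFT_Time`, `MAL_AOU`, `MAL_QOM`)
#'   and optional proximal variants suffixed `_prox`.
#' @param scope `"cross_sectional"` or `"longitudinal"`.
#' @param measures Clinical measures to include (default the three with
#'   proximal variants).
#' @param params Kinematic parameters to include.
#' @param holm_family `"scope"` (one family per grid, default),
#'   `"variant"` (separate families for total and proximal blocks) or
#'   `"none"`.
#' @return Tidy tibble: `scope`, `variant`, `measure`, `parameter`, `n`,
#'   `rho`, `p`, `p_holm`, `label`.
#' @export
correlation_grid <- function(kin, clinical,
                             scope = c("cross_sectional", "longitudinal"),
                             measures = c("FMA_UE", "WMFT_FAS", "WMFT_Time"),
                             params = kin_param_names,
                             holm_family = c("scope", "variant", "none")) {
  scope <- match.arg(scope)
  holm_family <- match.arg(holm_family)
  if ("arm" %in% names(kin)) kin <- dplyr::filter(kin, .data$arm == "paretic")
  params <- intersect(params, names(kin))

  if (scope == "cross_sectional") {
    obs <- dplyr::inner_join(kin, clinical, by = c("subject", "session"))
  } else {
    obs <- .longitudinal_deltas(kin, clinical, params)
  }

  cells <- tidyr::expand_grid(
    measure = measures,
    variant = c("total", "proximal"),
    parameter = params
  )
  cells <- dplyr::filter(
    cells,
    .data$variant == "total" |
      paste0(.data$measure, "_prox") %in% names(obs)
  )
  undefined <- character(0)
  res <- purrr::pmap_dfr(cells, function(measure, variant, parameter) {
    col <- if (variant == "total") measure else paste0(measure, "_prox")
    s <- tryCatch(
      spearman_rho(obs[[parameter]], obs[[col]]),
      reachkin_error_insufficient_data = function(e) NULL,
      reachkin_error_undefined_correlation = function(e) NULL
    )
    if (is.null(s)) {
      undefined <<- c(undefined, paste0(parameter, "/", col))
      s <- tibble::tibble(rho = NA_real_, p = NA_real_,
                          n = sum(complete.cases(obs[[parameter]],
                                                 obs[[col]])))
    }
    tibble::tibble(scope = scope, variant = variant, measure = measure,
                   parameter = parameter, n = s$n, rho = s$rho, p = s$p)
  })
  if (length(undefined)) {
    warn(sprintf("%d undefined correlation cells reported as NA (%s ...)",
                 length(undefined), undefined[1]))
  }
  res$p_holm <- switch(
    holm_family,
    scope = holm_adjust(res$p),
    variant = stats::ave(res$p, res$variant, FUN = holm_adjust),
    none = res$p
  )
  res$label <- hinkle_label(res$rho)
  res
}

# Per-subject post-minus-pre deltas of kinematic aggregates and clinical
# scores; subjects missing a session are dropped with a warning.
.longitudinal_deltas <- function(kin, clinical, params) {
  joined <- dplyr::inner_join(kin, clinical, by = c("subject", "session"))
  counts <- dplyr::count(joined, .data$subject)
  incomplete <- counts$subject[counts$n != 2L]
  if (length(incomplete)) {
    warn(paste0("dropping subjects without both sessions: ",
                paste(incomplete, collapse = ", ")))
    joined <- dplyr::filter(joined, !.data$subject %in% incomplete)
  }
  num_cols <- setdiff(names(joined)[vapply(joined, is.numeric, logical(1))],
                      "n_movements")
  joined |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(num_cols),
        ~ .x[session == "post"] - .x[session == "pre"]
      ),
      .groups = "drop"
    )
}

#' Group-level pre/post change table
#'
#' Bootstrapped paired t-tests of each variable across subjects (paired
#' by subject, pre vs post), with medians, quartiles, means, SDs,
#' percentile CIs, Holm-adjusted bootstrap p-values and
#' baseline-standardized Cohen's d. Used both for clinical outcome
#' measures and for the eleven kinematic aggregates.
#'
#' @param df Table with `subject`, `session` and the variable columns.
#' @param vars Variables to test (default: all kinematic parameters
#'   present).
#' @param directions Optional named vector (`"increase"`/`"decrease"`)
#'   used to sign-adjust `d` so that improvement is positive; see
#'   [kin_directions].
#' @param B,seed,method Passed to [boot_paired_t()].
#' @param alpha Significance level after Holm adjustment.
#' @return Tidy tibble, one row per variable, including `d`,
#'   `effect_label`, `p_boot`, `p_holm`, `significant`.
#' @export
group_change_table <- function(df, vars = NULL, directions = NULL,
                               B = 1000, seed = NULL,
                               method = c("studentized", "percentile"),
                               alpha = 0.05) {
  method <- match.arg(method)
  if ("arm" %in% names(df)) df <- dplyr::filter(df, .data$arm == "paretic")
  if (is.null(vars)) vars <- intersect(kin_param_names, names(df))
  wide <- df |>
    dplyr::select(dplyr::all_of(c("subject", "session", vars))) |>
    tidyr::pivot_wider(names_from = "session",
                       values_from = dplyr::all_of(vars),
                       names_glue = "{.value}@{session}")
  res <- purrr::imap_dfr(setNames(vars, vars), function(v, nm) {
    pre <- wide[[paste0(v, "@pre")]]
    post <- wide[[paste0(v, "@post")]]
    bt <- boot_paired_t(pre, post, B = B,
                        seed = if (is.null(seed)) NULL
                               else .derive_seed(seed, match(nm, vars)),
                        method = method)
    dir <- if (!is.null(directions) && nm %in% names(directions))
      directions[[nm]] else "increase"
    dd <- if (is.na(bt$d) || bt$sd_pre <= 0) bt$d
          else cohens_d(bt$mean_pre, bt$sd_pre, bt$mean_post, dir)
    dplyr::bind_cols(tibble::tibble(variable = nm),
                     glance(bt)[, c("n", "mean_pre", "sd_pre", "median_pre",
                                    "iqr_pre", "mean_post", "sd_post",
                                    "median_post", "iqr_post", "degenerate")],
                     tibble::tibble(mean_diff = bt$mean_diff,
                                    ci_low = bt$ci_low, ci_high = bt$ci_high,
                                    t = bt$t, p_boot = bt$p,
                                    d = dd, effect_label = effect_size_label(dd)))
  })
  res$p_holm <- holm_adjust(res$p_boot)
  res$significant <- !is.na(res$p_holm) & res$p_holm < alpha
  res
}

#' Subject-by-subject kinematic change table
#'
#' For each subject and kinematic parameter, a bootstrapped paired t-test
#' of the pre- vs post-intervention movements, paired by target and
#' repetition (the per-session reach battery uses a fixed randomized
#' target order shared across sessions). Optionally classifies each
#' subject's pre and post means against the non-paretic reference band
#' (mean +/- 1 SD of the pooled non-paretic aggregates): significant
#' changes whose pre and post means both lie inside the band are marked
#' not noteworthy.
#'
#' @param params Per-movement parameter table (paretic-arm rows used);
#'   needs `subject`, `session`, `target`, `rep` and parameter columns.
#' @param reference Optional non-paretic aggregate table (from
#'   [aggregate_parameters()] on non-paretic rows) used to build the
#'   reference bands.
#' @param vars Parameters to test.
#' @param B,seed,method Passed to [boot_paired_t()].
#' @param holm_family `"table"` (all subject x parameter cells, default),
#'   `"parameter"` (one family per parameter) or `"none"`.
#' @param alpha Significance level after Holm adjustment.
#' @return Tidy tibble, one row per subject x parameter.
#' @export
subject_change_table <- function(params, reference = NULL, vars = NULL,
                                 B = 1000, seed = NULL,
                                 method = c("studentized", "percentile"),
                                 holm_family = c("table", "parameter", "none"),
                                 alpha = 0.05) {
  method <- match.arg(method)
  holm_family <- match.arg(holm_family)
  if ("arm" %in% names(params)) {
    params <- dplyr::filter(params, .data$arm == "paretic")
  }
  if (is.null(vars)) vars <- intersect(kin_param_names, names(params))
  if (!"rep" %in% names(params)) params$rep <- 1L
  subjects <- unique(params$subject)
  grid <- tidyr::expand_grid(subject = subjects, variable = vars)
  res <- purrr::pmap_dfr(grid, function(subject, variable) {
    d <- params[params$subject == subject,
                c("session", "target", "rep", variable)]
    wide <- tidyr::pivot_wider(d, names_from = "session",
                               values_from = dplyr::all_of(variable))
    if (sum(complete.cases(wide$pre, wide$post)) < 2L) {
      warn(sprintf("subject %s: fewer than 2 paired movements for %s",
                   subject, variable))
      return(tibble::tibble(subject = subject, variable = variable,
                            n = sum(complete.cases(wide$pre, wide$post)),
                            mean_pre = NA_real_, sd_pre = NA_real_,
                            mean_post = NA_real_, sd_post = NA_real_,
                            mean_diff = NA_real_, t = NA_real_,
                            p_boot = NA_real_, d = NA_real_,
                            effect_label = NA_character_))
    }
    bt <- boot_paired_t(wide$pre, wide$post, B = B,
                        seed = if (is.null(seed)) NULL
                               else .derive_seed(seed, match(subject, subjects),
                                                 match(variable, vars)),
                        method = method)
    dir <- if (variable %in% names(kin_directions))
      kin_directions[[variable]] else "increase"
    dd <- if (is.na(bt$d) || bt$sd_pre <= 0) bt$d
          else cohens_d(bt$mean_pre, bt$sd_pre, bt$mean_post, dir)
    tibble::tibble(subject = subject, variable = variable, n = bt$n,
                   mean_pre = bt$mean_pre, sd_pre = bt$sd_pre,
                   mean_post = bt$mean_post, sd_post = bt$sd_post,
                   mean_diff = bt$mean_diff, t = bt$t, p_boot = bt$p,
                   d = dd, effect_label = effect_size_label(dd))
  })
  res$p_holm <- switch(
    holm_family,
    table = holm_adjust(res$p_boot),
    parameter = stats::ave(res$p_boot, res$variable, FUN = holm_adjust),
    none = res$p_boot
  )
  res$significant <- !is.na(res$p_holm) & res$p_holm < alpha
  if (!is.null(reference)) {
    bands <- purrr::map_dfr(setNames(vars, vars), function(v) {
      b <- nonparetic_band(reference[[v]])
      tibble::tibble(band_low = b$low, band_high = b$high)
    }, .id = "variable")
    res <- dplyr::left_join(res, bands, by = "variable")
    res$pre_within <- res$mean_pre >= res$band_low & res$mean_pre <= res$band_high
    res$post_within <- res$mean_post >= res$band_low & res$mean_post <= res$band_high
    res$noteworthy <- res$significant & !(res$pre_within & res$post_within)
  }
  res
}

#' Default minimal clinically important differences
#'
#' Literature-typical MCID values for the clinical outcome measures, in
#' the units of each scale. These are configurable defaults, not study
#' constants: replace any entry with the values appropriate for your
#' population.
#'
#' @return Tibble with `measure`, `mcid`, `direction`.
#' @export
default_mcid_table <- function() {
  tibble::tibble(
    measure = c("FMA_UE", "WMFT_FAS", "WMFT_Time", "MAL_AOU", "MAL_QOM"),
    mcid = c(5.25, 0.37, 1.5, 0.5, 0.5),
    direction = c("increase", "increase", "decrease", "increase", "increase")
  )
}

#' MCID flags and responder summary
#'
#' Flags, per subject and clinical measure, whether the pre-to-post
#' improvement (direction-aware) meets or exceeds the minimal clinically
#' important difference; a change exactly equal to the MCID is flagged.
#' A responder is a subject with at least one flagged measure.
#'
#' @param clinical Clinical-scores table with `subject`, `session` and
#'   measure columns.
#' @param mcid MCID table as returned by [default_mcid_table()]; measures
#'   present in the data but absent from the table are skipped with a
#'   warning.
#' @return Tibble, one row per subject x measure, with `delta`,
#'   `improvement`, `mcid`, `flagged`.
#' @seealso [responder_summary()]
#' @export
mcid_flags <- function(clinical, mcid = default_mcid_table()) {
  if (any(mcid$mcid <= 0)) {
    abort("MCID entries must be positive",
          class = "reachkin_error_invalid_argument")
  }
  present <- intersect(.clinical_meta$measure, names(clinical))
  skipped <- setdiff(present, mcid$measure)
  if (length(skipped)) {
    warn(paste0("no MCID entry for: ", paste(skipped, collapse = ", ")))
    present <- setdiff(present, skipped)
  }
  long <- clinical |>
    dplyr::select(dplyr::all_of(c("subject", "session", present))) |>
    tidyr::pivot_longer(dplyr::all_of(present), names_to = "measure") |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  long |>
    dplyr::left_join(mcid, by = "measure") |>
    dplyr::mutate(
      delta = .data$post - .data$pre,
      improvement = ifelse(.data$direction == "decrease",
                           -.data$delta, .data$delta),
      flagged = .data$improvement >= .data$mcid
    ) |>
    dplyr::select(dplyr::all_of(c("subject", "measure", "pre", "post",
                                  "delta", "improvement", "mcid", "flagged")))
}

#' @rdname mcid_flags
#' @param flags Output of [mcid_flags()].
#' @return `responder_summary()`: one row per subject with `n_flagged`
#'   and `responder`.
#' @export
responder_summary <- function(flags) {
  flags |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(n_flagged = sum(.data$flagged, na.rm = TRUE),
                     responder = .data$n_flagged >= 1L,
                     .groups = "drop")
}
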