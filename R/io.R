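# CSV interfaces. Marker data travel in long format (one row per frame x
# marker), clinical scores as one row per subject x session. Units are cm
# and seconds throughout.

# Accepted aliases for the canonical marker labels (anatomical synonyms
# and common capture-lab conventions).
.marker_aliases <- c(
  CLAV = "CLAV", SJN = "CLAV", SUPRASTERNAL_NOTCH = "CLAV",
  STRN = "STRN", XIPH = "STRN", XIPHOID = "STRN",
  C7 = "C7", T10 = "T10"
)

.canonical_label <- function(labels) {
  up <- toupper(labels)
  mapped <- unname(.marker_aliases[up])
  ifelse(is.na(mapped), labels, mapped)
}

#' Write trials to a long-format marker CSV
#'
#' @param trials A `reach_trial` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(trials, path) {
  if (inherits(trials, "reach_trial")) trials <- list(trials)
  df <- dplyr::bind_rows(lapply(trials, as_tibble))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format marker CSV
#'
#' Validates the schema, maps marker-label aliases to canonical names and
#' returns the long table; use [split_trials()] to obtain per-trial
#' tibbles for [reach_parameters()].
#'
#' @param path CSV with columns `subject`, `session`, `arm`, `target`,
#'   `frame`, `time_s`, `marker`, `x_cm`, `y_cm`, `z_cm` (and optionally
#'   `side`).
#' @return A tibble.
#' @export
read_markers_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "reachkin_error_io")
  }
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject", "session", "arm", "target", "frame", "time_s",
            "marker", "x_cm", "y_cm", "z_cm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0(path, ": missing columns ", paste(missing, collapse = ", ")),
          class = "reachkin_error_schema")
  }
  if (!all(is.finite(df$x_cm) & is.finite(df$y_cm) & is.finite(df$z_cm))) {
    abort(paste0(path, ": non-finite marker positions"),
          class = "reachkin_error_parse")
  }
  df$marker <- .canonical_label(df$marker)
  df
}

#' Split a long marker table into per-trial tables
#'
#' @param df Long marker tibble ([read_markers_csv()] output).
#' @return Named list of one-trial tibbles (key
#'   `subject/session/arm/target`).
#' @export
split_trials <- function(df) {
  key <- interaction(df$subject, df$session, df$arm, df$target,
                     sep = "/", drop = TRUE)
  split(df, key)
}

#' Read a clinical-scores CSV
#'
#' One row per subject x session; columns `subject`, `session` plus any
#' of the outcome measures (`FMA_UE`, `WMFT_FAS`, `WMFT_Time`, `MAL_AOU`,
#' `MAL_QOM`, and `_prox` variants). Scale ranges are validated
#' (FMA-UE 0-66; FAS and MAL 0-5; WMFT-Time > 0).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "reachkin_error_io")
  }
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("subject", "session") %in% names(df))) {
    abort(paste0(path, ": needs subject and session columns"),
          class = "reachkin_error_schema")
  }
  if (!all(df$session %in% c("pre", "post"))) {
    abort(paste0(path, ": session must be 'pre' or 'post'"),
          class = "reachkin_error_schema")
  }
  chk <- function(col, lo, hi) {
    if (col %in% names(df) &&
        any(df[[col]] < lo | df[[col]] > hi, na.rm = TRUE)) {
      abort(sprintf("%s: %s outside [%g, %g]", path, col, lo, hi),
            class = "reachkin_error_schema")
    }
  }
  chk("FMA_UE", 0, 66); chk("WMFT_FAS", 0, 5)
  chk("MAL_AOU", 0, 5); chk("MAL_QOM", 0, 5)
  if ("WMFT_Time" %in% names(df) && any(df$WMFT_Time <= 0, na.rm = TRUE)) {
    abort(paste0(path, ": WMFT_Time must be positive"),
          class = "reachkin_error_schema")
  }
  df
}

#' Write ground truth and configuration to a sidecar JSON
#'
#' @param truth Ground-truth tibble (e.g. `sim_cohort()$truth`).
#' @param config Optional list of generative settings stored alongside.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path, config = NULL) {
  payload <- list(truth = truth)
  if (!is.null(config)) payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
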