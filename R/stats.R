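#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (exact where available, otherwise the standard approximation).
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @return One-row tibble with `rho`, `p`, `n`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)) # rho = 0.8
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) {
    abort("need at least 4 complete pairs",
          class = "reachkin_error_insufficient_data")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          class = "reachkin_error_undefined_correlation")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Holm step-down multiple-testing adjustment
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order (family-wise error
#'   control); empty input gives empty output.
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]",
          class = "reachkin_error_invalid_argument")
  }
  p.adjust(p, method = "holm")
}

#' Hinkle rule-of-thumb correlation label
#'
#' Labels the magnitude of a correlation coefficient: high (0.70-1.00),
#' moderate (0.50-0.70), low (0.30-0.50), negligible (0.00-0.30), with
#' each boundary assigned to the higher class (0.50 is moderate, 0.70 is
#' high).
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @return Character vector of labels.
#' @export
hinkle_label <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort("|r| must not exceed 1", class = "reachkin_error_invalid_argument")
  }
  a <- abs(r)
  dplyr::case_when(
    is.na(a) ~ NA_character_,
    a >= 0.70 ~ "high",
    a >= 0.50 ~ "moderate",
    a >= 0.30 ~ "low",
    TRUE ~ "negligible"
  )
}

#' Baseline-standardized Cohen's d
#'
#' Pre-to-post standardized mean change using the pre-intervention
#' standard deviation as the denominator:
#' \eqn{d = (\bar{x}_{post} - \bar{x}_{pre}) / s_{pre}}. When the measure
#' improves by decreasing (e.g. task time, movement time, velocity-peak
#' count), the sign is flipped so that improvement is positive.
#'
#' @param mean_pre,sd_pre,mean_post Summary statistics (vectorized).
#' @param improvement_direction `"increase"` (default) or `"decrease"`.
#' @return Effect size(s) d.
#' @seealso [effect_size_label()]
#' @examples
#' cohens_d(32.20, 9.60, 39.50) # 0.76
#' @export
cohens_d <- function(mean_pre, sd_pre, mean_post,
                     improvement_direction = c("increase", "decrease")) {
  improvement_direction <- match.arg(improvement_direction)
  if (any(sd_pre <= 0, na.rm = TRUE)) {
    abort("effect size undefined: pre-intervention SD must be > 0",
          class = "reachkin_error_undefined_effect_size")
  }
  d <- (mean_post - mean_pre) / sd_pre
  if (improvement_direction == "decrease") d <- -d
  d
}

#' Effect-size magnitude label
#'
#' Cohen's conventions on |d|: >= 0.80 large, >= 0.50 medium, >= 0.20
#' small, otherwise negligible.
#'
#' @param d Effect size(s).
#' @return Character vector of labels.
#' @export
effect_size_label <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    is.na(a) ~ NA_character_,
    a >= 0.80 ~ "large",
    a >= 0.50 ~ "medium",
    a >= 0.20 ~ "small",
    TRUE ~ "negligible"
  )
}

#' Bootstrapped paired t-test
#'
#' Paired pre/post comparison for small samples: the t statistic on the
#' paired differences plus a nonparametric bootstrap over pairs
#' (resampled with replacement). The reported confidence interval is the
#' percentile interval of the mean difference. Two p-value constructions
#' are available: `"studentized"` (default) compares the observed t
#' statistic with the bootstrap distribution of centered, re-studentized
#' t statistics, which is well calibrated down to n of about 10;
#' `"percentile"` inverts the percentile interval,
#' \eqn{p = 2\min(P(\bar{d}^* \le 0), P(\bar{d}^* \ge 0))}, with
#' add-one continuity handling. Both use (1 + count)/(B + 1) counting.
#'
#' @param pre,post Paired numeric vectors of equal length (n >= 2).
#' @param B Number of bootstrap resamples (>= 100; default 1000).
#' @param seed Optional integer seed; results are reproducible under a
#'   fixed seed and leave the caller's RNG state untouched.
#' @param ci_level Confidence level for the percentile CI (default 0.95).
#' @param method P-value construction, see above.
#' @return An object of class `boot_paired_t`; see [tidy.boot_paired_t()]
#'   and [glance.boot_paired_t()]. Zero-variance differences yield a
#'   degenerate result with an undefined (NA) p-value.
#' @export
boot_paired_t <- function(pre, post, B = 1000, seed = NULL,
                          ci_level = 0.95,
                          method = c("studentized", "percentile")) {
  method <- match.arg(method)
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must have equal length",
          class = "reachkin_error_invalid_argument")
  }
  ok <- complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2L) {
    abort("need at least 2 complete pairs",
          class = "reachkin_error_insufficient_data")
  }
  if (B < 100) {
    abort("B must be at least 100", class = "reachkin_error_invalid_argument")
  }
  d <- post - pre
  m <- mean(d); s <- sd(d)
  sd_pre <- sd(pre)
  out <- list(
    n = n, B = as.integer(B), method = method, seed = seed,
    mean_pre = mean(pre), sd_pre = sd_pre,
    mean_post = mean(post), sd_post = sd(post),
    median_pre = median(pre), iqr_pre = unname(diff(quantile(pre, c(.25, .75)))),
    median_post = median(post), iqr_post = unname(diff(quantile(post, c(.25, .75)))),
    mean_diff = m,
    d = if (sd_pre > 0) m / sd_pre else NA_real_,
    degenerate = s == 0
  )
  if (out$degenerate) {
    out$t <- NA_real_
    out$p <- NA_real_
    out$ci_low <- m; out$ci_high <- m
    if (m == 0) out$d <- 0
    class(out) <- "boot_paired_t"
    return(out)
  }
  out$t <- m / (s / sqrt(n))

  run <- function() {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    dm <- matrix(d[idx], nrow = B)
    bmean <- rowMeans(dm)
    ci <- unname(quantile(bmean, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)))
    if (method == "percentile") {
      p <- 2 * min((1 + sum(bmean <= 0)) / (B + 1),
                   (1 + sum(bmean >= 0)) / (B + 1))
    } else {
      bsd <- sqrt(pmax(0, (rowSums(dm^2) - n * bmean^2) / (n - 1)))
      tstar <- (bmean - m) / (bsd / sqrt(n))
      tstar <- tstar[is.finite(tstar)]
      p <- (1 + sum(abs(tstar) >= abs(out$t))) / (length(tstar) + 1)
    }
    list(p = min(p, 1), ci = ci)
  }
  res <- if (is.null(seed)) run() else .with_seed(seed, run())
  out$p <- res$p
  out$ci_low <- res$ci[1]
  out$ci_high <- res$ci[2]
  class(out) <- "boot_paired_t"
  out
}

#' @export
print.boot_paired_t <- function(x, ...) {
  cat("Bootstrapped paired t-test (", x$method, ", B = ", x$B, ")\n", sep = "")
  cat(sprintf("  n = %d, mean diff = %.4g [%.4g, %.4g], t = %.3f, p = %.4g\n",
              x$n, x$mean_diff, x$ci_low, x$ci_high, x$t, x$p))
  cat(sprintf("  Cohen's d (baseline SD) = %.3f (%s)%s\n", x$d,
              effect_size_label(x$d),
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' Tidy a bootstrapped paired t-test
#'
#' @param x A [boot_paired_t()] object.
#' @param ... Unused.
#' @return One-row tibble with the estimate, percentile CI, t statistic,
#'   bootstrap p-value and baseline-standardized effect size.
#' @method tidy boot_paired_t
#' @export
tidy.boot_paired_t <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_diff, ci_low = x$ci_low, ci_high = x$ci_high,
    statistic = x$t, p.value = x$p, d = x$d,
    effect_label = effect_size_label(x$d)
  )
}

#' @rdname tidy.boot_paired_t
#' @return `glance()`: one-row tibble of test-level metadata and the
#'   pre/post summary statistics.
#' @method glance boot_paired_t
#' @export
glance.boot_paired_t <- function(x, ...) {
  tibble::tibble(
    n = x$n, B = x$B, method = x$method, degenerate = x$degenerate,
    mean_pre = x$mean_pre, sd_pre = x$sd_pre,
    mean_post = x$mean_post, sd_post = x$sd_post,
    median_pre = x$median_pre, iqr_pre = x$iqr_pre,
    median_post = x$median_post, iqr_post = x$iqr_post
  )
}

#' Non-paretic reference band
#'
#' The interval mean +/- one standard deviation of a kinematic parameter
#' over non-paretic-arm observations. Paretic values falling inside the
#' band are considered comparable to unaffected-arm performance, so
#' pre-to-post changes within the band are not flagged as noteworthy.
#'
#' @param values Non-paretic aggregate values of one parameter (>= 2).
#' @return A `reference_band` list with `low`, `high`, `mean`, `sd`.
#' @export
nonparetic_band <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    abort("need at least 2 non-paretic observations",
          class = "reachkin_error_undefined_band")
  }
  m <- mean(values); s <- sd(values)
  structure(list(low = m - s, high = m + s, mean = m, sd = s),
            class = "reference_band")
}

#' @rdname nonparetic_band
#' @param value Value(s) to classify.
#' @param band A `reference_band`.
#' @return `within_band()`: logical vector.
#' @export
within_band <- function(value, band) {
  stopifnot(inherits(band, "reference_band"))
  value >= band$low & value <= band$high
}
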