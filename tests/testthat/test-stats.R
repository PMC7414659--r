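test_that("Spearman correlation matches hand-computed examples", {
  expect_equal(spearman_rho(1:4, c(2, 4, 6, 8))$rho, 1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 2
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4))$rho, 0.8)
  expect_equal(spearman_rho(1:4, rev(c(1, 3, 2, 4)))$rho, -0.8)
  expect_error(spearman_rho(1:4, rep(2, 4)),
               class = "reachkin_error_undefined_correlation")
  expect_error(spearman_rho(1:3, 1:3),
               class = "reachkin_error_insufficient_data")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(31)
  x <- rnorm(25); y <- rnorm(25)
  r0 <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, r0)
  expect_equal(spearman_rho(x, y^3 + 5 * y)$rho, r0)
})

test_that("Holm adjustment follows the step-down recipe", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  set.seed(32)
  p <- runif(40)
  h <- holm_adjust(p)
  expect_true(all(h >= p))
  expect_true(all(pmin(1, p * 40) >= h))  # Bonferroni dominates Holm
})

test_that("Hinkle labels use the inclusive-upper-boundary convention", {
  expect_equal(hinkle_label(-0.73), "high")
  expect_equal(hinkle_label(0), "negligible")
  expect_equal(hinkle_label(0.50), "moderate")
  expect_equal(hinkle_label(0.30), "low")
  expect_equal(hinkle_label(0.70), "high")
  expect_error(hinkle_label(1.2), class = "reachkin_error_invalid_argument")
})

test_that("baseline-standardized Cohen's d matches its worked examples", {
  expect_equal(round(cohens_d(32.20, 9.60, 39.50), 2), 0.76)
  expect_equal(round(cohens_d(39.11, 12.21, 47.67), 2), 0.70)
  expect_equal(cohens_d(5, 2, 5), 0)
  # decrease-is-better measures flip sign so improvement is positive
  expect_equal(round(cohens_d(32.82, 25.33, 24.04, "decrease"), 2), 0.35)
  expect_error(cohens_d(1, 0, 2), class = "reachkin_error_undefined_effect_size")
  expect_equal(effect_size_label(c(0.1, 0.2, 0.5, 0.8)),
               c("negligible", "small", "medium", "large"))
})

test_that("bootstrapped paired t-test flags degenerate differences", {
  x <- c(1, 2, 3, 4, 5)
  bt <- boot_paired_t(x, x, B = 200)
  expect_true(bt$degenerate)
  expect_equal(bt$mean_diff, 0)
  expect_equal(bt$d, 0)
  expect_true(is.na(bt$p))
})

test_that("bootstrapped paired t-test is reproducible and detects a unit shift", {
  set.seed(41)
  pre <- rnorm(30)
  post <- pre + 1 + rnorm(30, sd = 0.5)
  b1 <- boot_paired_t(pre, post, B = 1000, seed = 5)
  b2 <- boot_paired_t(pre, post, B = 1000, seed = 5)
  expect_identical(tidy(b1), tidy(b2))
  expect_lt(b1$p, 0.01)

  # a unit shift at n = 30 is essentially always detected
  hits <- 0L
  for (r in 1:200) {
    pre <- rnorm(30)
    post <- pre + 1
    bt <- boot_paired_t(pre, post, B = 1000)
    if (bt$ci_low > 0) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("tidy and glance return one-row summaries", {
  bt <- boot_paired_t(rnorm(12), rnorm(12), B = 200, seed = 3)
  td <- tidy(bt)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_named(td, c("estimate", "ci_low", "ci_high", "statistic",
                     "p.value", "d", "effect_label"))
  gl <- glance(bt)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n, 12L)
  expect_equal(gl$B, 200L)
})

test_that("non-paretic reference bands classify values", {
  b <- nonparetic_band(c(8, 10, 12, 10))
  expect_equal(b$mean, 10)
  expect_true(within_band(10, b))
  expect_false(within_band(10 + 2 * b$sd, b))
  expect_error(nonparetic_band(5), class = "reachkin_error_undefined_band")
})

test_that("MCID flags are direction-aware with an inclusive boundary", {
  clinical <- tibble::tibble(
    subject = rep(c("A", "B", "C"), each = 2),
    session = rep(c("pre", "post"), 3),
    FMA_UE = c(30, 35.25,  # +5.25 = exactly the MCID -> flagged
               30, 28,     # worse -> not flagged
               30, 31),    # +1 < MCID -> not flagged
    WMFT_Time = c(20, 25,   # slower (worse) -> not flagged
                  20, 18.5, # 1.5 s faster = exactly the MCID -> flagged
                  20, 19.9)
  )
  fl <- mcid_flags(clinical)
  get <- function(s, m) fl$flagged[fl$subject == s & fl$measure == m]
  expect_true(get("A", "FMA_UE"))
  expect_false(get("B", "FMA_UE"))
  expect_false(get("C", "FMA_UE"))
  expect_false(get("A", "WMFT_Time"))
  expect_true(get("B", "WMFT_Time"))
  rs <- responder_summary(fl)
  expect_equal(sum(rs$responder), 2L)
  expect_equal(rs$n_flagged[rs$subject == "C"], 0L)
})

test_that("correlation grid returns rho = 1 when kinematics equal the score", {
  agg <- tidyr::expand_grid(subject = sprintf("S%d", 1:8),
                            session = c("pre", "post"))
  agg$arm <- "paretic"
  set.seed(51)
  agg$LDJ <- rnorm(16, -12, 2)
  clinical <- tibble::tibble(subject = agg$subject, session = agg$session,
                             FMA_UE = agg$LDJ)
  g <- correlation_grid(agg, clinical, "cross_sectional",
                        measures = "FMA_UE", params = "LDJ")
  expect_equal(g$rho, 1)
  expect_equal(g$label, "high")
  gl <- correlation_grid(agg, clinical, "longitudinal",
                         measures = "FMA_UE", params = "LDJ")
  expect_equal(gl$rho, 1)
})

test_that("longitudinal grids drop subjects missing a session, with a warning", {
  agg <- tidyr::expand_grid(subject = sprintf("S%d", 1:6),
                            session = c("pre", "post"))
  agg$arm <- "paretic"
  set.seed(52)
  agg$MT <- rnorm(12, 2.4, 0.4)
  clinical <- tibble::tibble(subject = agg$subject, session = agg$session,
                             FMA_UE = 60 - 5 * agg$MT + rnorm(12, 0, 0.5))
  agg_missing <- agg[!(agg$subject == "S3" & agg$session == "post"), ]
  expect_warning(
    g <- correlation_grid(agg_missing, clinical, "longitudinal",
                          measures = "FMA_UE", params = "MT"),
    "S3"
  )
  expect_equal(g$n, 5)
})
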