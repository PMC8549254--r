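# Contingency statistics, group comparisons, logistic screening and the
# noncentral-t sample-size iteration.

test_that("odds ratios and Woolf intervals match hand computation", {
  o <- odds_ratio(contingency_2x2(14, 18, 23, 10))   # ischemic x responder
  expect_equal(round(o$or, 2), 0.34)
  expect_equal(round(o$ci_lower, 2), 0.12)
  expect_equal(round(o$ci_upper, 2), 0.94)

  o2 <- odds_ratio(contingency_2x2(34, 3, 22, 6))    # LBBB x responder
  expect_equal(round(o2$or, 2), 3.09)
  expect_equal(round(o2$ci_lower, 2), 0.70)
  expect_equal(round(o2$ci_upper, 2), 13.66)

  # symmetry: equal cells give OR 1; swapping exposure inverts the OR
  expect_equal(odds_ratio(c(7, 7, 7, 7))$or, 1)
  a <- odds_ratio(c(12, 5, 9, 17))
  b <- odds_ratio(c(9, 17, 12, 5))
  expect_equal(a$or * b$or, 1, tolerance = 1e-12)

  # zero cell: Haldane-Anscombe correction, flagged
  z <- odds_ratio(c(10, 0, 5, 5))
  expect_true(z$corrected)
  expect_true(is.finite(z$or))
  expect_equal(z$or, 10.5 * 5.5 / (0.5 * 5.5), tolerance = 1e-12)
})

test_that("group comparisons pick the right test and calibrate correctly", {
  # chi-squared (uncorrected) on the septal-contribution response table
  df <- data.frame(neg = rep(c(TRUE, TRUE, FALSE, FALSE), c(16, 12, 21, 16)),
                   resp = rep(c(TRUE, FALSE, TRUE, FALSE), c(16, 12, 21, 16)))
  g <- group_compare(df, "neg", "resp")
  expect_match(g$method, "chi-squared")
  expect_equal(round(g$p_value, 2), 0.98)

  # identical groups: t = 0, p = 1
  d2 <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c(TRUE, FALSE), each = 3))
  t2 <- group_compare(d2, "v", "g")
  expect_equal(t2$statistic, 0, tolerance = 1e-12)
  expect_equal(t2$p_value, 1, tolerance = 1e-12)

  # zero variance in both groups: undefined, flagged
  d3 <- data.frame(v = rep(5, 8), g = rep(c(TRUE, FALSE), 4))
  t3 <- group_compare(d3, "v", "g")
  expect_true(is.na(t3$p_value))
  expect_match(t3$flags, "zero variance", all = FALSE)

  # Fisher fallback when an expected count drops below 5
  d4 <- data.frame(v = rep(c(TRUE, FALSE), c(3, 17)), g = rep(c(TRUE, FALSE), 10))
  expect_match(group_compare(d4, "v", "g")$method, "Fisher")

  # paired variant
  d5 <- data.frame(base = c(200, 180, 240, 210), fu = c(150, 170, 200, 160))
  p5 <- group_compare(d5, c("base", "fu"), paired = TRUE)
  expect_match(p5$method, "paired")
  expect_equal(p5$p_value,
               stats::t.test(d5$base, d5$fu, paired = TRUE)$p.value)
})

test_that("the unpaired t-test holds its nominal type-I error under the null", {
  set.seed(123)
  reps <- 1e4
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- data.frame(v = stats::rnorm(40), g = rep(c(TRUE, FALSE), each = 20))
    p[i] <- group_compare(d, "v", "g")$p_value
  }
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.01 / 0.05)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("logistic screening matches the closed-form 2x2 odds ratio", {
  df <- data.frame(responder = rep(c(TRUE, FALSE, TRUE, FALSE), c(14, 18, 23, 10)),
                   ischemic = rep(c(TRUE, TRUE, FALSE, FALSE), c(14, 18, 23, 10)))
  sc <- logistic_screen(df, outcome = "responder", candidates = "ischemic")
  expect_equal(sc$univariable$or, 14 * 10 / (18 * 23), tolerance = 1e-6)
  expect_equal(round(sc$univariable$or, 2), 0.34)
  expect_true(sc$univariable$included)   # p = 0.04 < 0.25

  # independent predictor at large n: excluded, multivariable empty
  set.seed(31)
  big <- data.frame(responder = stats::runif(4000) < 0.5,
                    x = stats::runif(4000) < 0.5)
  sc2 <- logistic_screen(big, outcome = "responder", candidates = "x")
  expect_gt(sc2$univariable$p, 0.25)
  expect_false(sc2$univariable$included)
  expect_null(sc2$multivariable)

  # complete separation is flagged with a non-finite OR
  sep <- data.frame(responder = rep(c(TRUE, FALSE), each = 10),
                    x = rep(c(TRUE, FALSE), each = 10))
  sc3 <- suppressWarnings(logistic_screen(sep, outcome = "responder",
                                          candidates = "x"))
  expect_true(sc3$univariable$separation)
  expect_false(is.finite(sc3$univariable$or))
})

test_that("multivariable screening applies the 0.25 entry and 0.05 retention rules", {
  co <- generate_cohort(cohort_spec(seed = 3))
  df <- svdecomp:::augment_cohort(co)
  df$male <- df$sex == "M"
  df$qrs150 <- df$qrs_ms >= 150
  sc <- logistic_screen(df, outcome = "responder",
                        candidates = c("ischemic", "lbbb", "qrs150", "male",
                                       "sv_long_pct", "sv_lat_pct", "sv_sept_pct"))
  expect_identical(sc$included, sc$univariable$predictor[sc$univariable$p < 0.25])
  expect_true("ischemic" %in% sc$included)   # p = 0.04 on the exact-count layout
  if (!is.null(sc$multivariable)) {
    expect_identical(sc$multivariable$retained, sc$multivariable$p < 0.05)
    expect_true(all(sc$multivariable$ci_lower <= sc$multivariable$or &
                      sc$multivariable$or <= sc$multivariable$ci_upper))
  }
})

test_that("sample size iteration reproduces classical results and bounds", {
  r <- sample_size_t(delta = 1, sd = 1, ratio = 1, alpha = 0.05, power = 0.8)
  expect_equal(r$n, 17L)
  expect_gte(r$power, 0.8)
  # exhaustive check of minimality around the solution
  pw <- function(n) {
    ncp <- 1 / sqrt(2 / n); df <- 2 * n - 2
    tc <- stats::qt(0.975, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
  expect_lt(pw(16), 0.8)
  expect_gte(pw(17), 0.8)

  # infinite effect: the minimum n = 2 (df >= 1)
  expect_equal(sample_size_t(delta = 1e6, sd = 1)$n, 2L)

  # monotonicity: non-increasing in |delta|, non-decreasing in sd
  n_small <- sample_size_t(delta = 0.5, sd = 1)$n
  n_large <- sample_size_t(delta = 1.5, sd = 1)$n
  expect_gte(n_small, sample_size_t(delta = 1, sd = 1)$n)
  expect_lte(n_large, sample_size_t(delta = 1, sd = 1)$n)
  expect_gte(sample_size_t(delta = 1, sd = 2)$n, sample_size_t(delta = 1, sd = 1)$n)

  expect_error(sample_size_t(0, 1), "nonzero")
  expect_error(sample_size_t(1, 0), "positive")
})

test_that("the reconstructed lateral-contribution power run lands in the mid-90s", {
  r <- sample_size_t(delta = 7, sd = 16, ratio = 28 / 37, alpha = 0.05, power = 0.8)
  expect_gte(r$n, 90); expect_lte(r$n, 100)
})
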