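# Outcome statistics: odds ratios with Woolf confidence intervals, group
# comparisons (Student t / chi-squared / Fisher), logistic predictor
# screening, and two-sample t-test sample size at unequal allocation.

#' Odds ratio of a 2x2 table with Woolf 95% confidence interval
#'
#' OR = ad/(bc); CI = exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' With any zero cell the Haldane-Anscombe correction (0.5 added to every
#' cell) is applied and flagged.
#'
#' @param t a [contingency_2x2] or numeric vector `c(a, b, c, d)`.
#' @param conf_z normal quantile for the CI (1.96 for 95%).
#' @return An object of class `or2x2`: list with `or`, `ci_lower`,
#'   `ci_upper`, `counts`, `corrected`.
#' @export
odds_ratio <- function(t, conf_z = 1.96) {
  x <- as.numeric(t)
  if (length(x) != 4L || any(x < 0)) stop("need four non-negative counts a, b, c, d")
  corrected <- any(x == 0)
  xc <- if (corrected) x + 0.5 else x
  or <- xc[1] * xc[4] / (xc[2] * xc[3])
  se <- sqrt(sum(1 / xc))
  structure(list(or = or,
                 ci_lower = exp(log(or) - conf_z * se),
                 ci_upper = exp(log(or) + conf_z * se),
                 counts = x, corrected = corrected),
            class = "or2x2")
}

#' @export
print.or2x2 <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f)%s\n", x$or, x$ci_lower, x$ci_upper,
              if (x$corrected) "  [Haldane-Anscombe 0.5 correction]" else ""))
  invisible(x)
}

#' Compare a variable between two groups
#'
#' Continuous variables: unpaired two-sided Student t-test (equal
#' variances), or a paired t-test for baseline/follow-up pairs.  Categorical
#' variables: Pearson chi-squared without continuity correction, falling
#' back to Fisher's exact test when any expected cell count is below 5.
#'
#' @param data a data frame (e.g. a `cohort_table`; the derived columns
#'   `delta_lvesv_pct` and `responder` are available for cohorts).
#' @param variable column name of the variable to compare — or, with
#'   `paired = TRUE`, a length-2 vector of baseline and follow-up columns.
#' @param grouping column name of a two-level grouping variable (ignored
#'   when `paired = TRUE`).
#' @param paired paired baseline/follow-up comparison.
#' @return An object of class `group_comparison`: list with `method`,
#'   `statistic`, `p_value`, `estimate`, `flags`.
#' @export
group_compare <- function(data, variable, grouping = "responder", paired = FALSE) {
  if (inherits(data, "cohort_table")) data <- augment_cohort(data)
  flags <- character(0)
  if (paired) {
    if (length(variable) != 2L) stop("paired comparison needs two column names")
    x <- data[[variable[1]]]; y <- data[[variable[2]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) stop("need at least 2 complete pairs")
    tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
    return(structure(list(method = "paired t-test", statistic = unname(tt$statistic),
                          p_value = tt$p.value, estimate = unname(tt$estimate),
                          flags = flags), class = "group_comparison"))
  }
  g <- data[[grouping]]
  v <- data[[variable]]
  if (is.null(g) || is.null(v)) stop("variable or grouping column not found")
  ok <- !is.na(g) & !is.na(v)
  g <- g[ok]; v <- v[ok]
  dropped <- sum(!ok)
  lev <- unique(g)
  if (length(lev) != 2L) stop("grouping must have exactly two levels")
  if (is.numeric(v)) {
    v1 <- v[g == lev[1]]; v2 <- v[g == lev[2]]
    if (length(v1) < 2L || length(v2) < 2L) stop("need >= 2 observations per group")
    if (stats::var(v1) == 0 && stats::var(v2) == 0) {
      return(structure(list(method = "unpaired t-test", statistic = NA_real_,
                            p_value = NA_real_, estimate = mean(v1) - mean(v2),
                            flags = "zero variance in both groups: test undefined"),
                       class = "group_comparison"))
    }
    tt <- stats::t.test(v1, v2, var.equal = TRUE)
    out <- list(method = "unpaired t-test (equal variances)",
                statistic = unname(tt$statistic), p_value = tt$p.value,
                estimate = unname(diff(rev(tt$estimate))), flags = flags)
  } else {
    tab <- table(factor(v), factor(g))
    if (any(dim(tab) < 2L)) {
      return(structure(list(method = "chi-squared", statistic = NA_real_,
                            p_value = NA_real_, estimate = NA_real_,
                            flags = "degenerate table: a level is absent"),
                       class = "group_comparison"))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      out <- list(method = "Fisher exact", statistic = NA_real_,
                  p_value = ft$p.value, estimate = unname(ft$estimate), flags = flags)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      out <- list(method = "Pearson chi-squared (uncorrected)",
                  statistic = unname(ct$statistic), p_value = ct$p.value,
                  estimate = NA_real_, flags = flags)
    }
  }
  if (dropped > 0) out$flags <- c(out$flags, sprintf("%d record(s) dropped (missing)", dropped))
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g", x$method, x$p_value))
  if (!is.na(x$statistic)) cat(sprintf(" (statistic %.3f)", x$statistic))
  cat("\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Logistic-regression predictor screening
#'
#' Fits a univariable binomial logistic model (iteratively reweighted least
#' squares via [stats::glm]) for every candidate predictor; candidates with
#' a Wald p-value below `enter_p` (default 0.25) enter a joint multivariable
#' model, whose predictors are marked as retained when p < `retain_p`
#' (default 0.05).  Odds ratios carry Wald 95% confidence intervals
#' (`exp(b +/- 1.96 se)`).  A diverging coefficient (separation) is flagged
#' and its odds ratio reported as non-finite.
#'
#' @param cohort a `cohort_table` or data frame.
#' @param outcome column name of the binary outcome; default `"responder"`
#'   (derived from the LVESV volumes when absent).
#' @param candidates character vector of predictor column names.
#' @param enter_p univariable inclusion threshold.
#' @param retain_p multivariable retention threshold.
#' @return An object of class `logistic_screen`: list with `univariable`
#'   and `multivariable` data frames, `included` predictor names and
#'   `converged` flag.
#' @export
logistic_screen <- function(cohort, outcome = "responder", candidates,
                            enter_p = 0.25, retain_p = 0.05) {
  df <- if (inherits(cohort, "cohort_table")) augment_cohort(cohort) else cohort
  y <- df[[outcome]]
  if (is.null(y)) stop(sprintf("outcome column '%s' not found", outcome))
  y <- as.logical(y)
  if (length(unique(stats::na.omit(y))) != 2L)
    stop("outcome must be binary with both classes present")
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  wald_row <- function(fit, term) {
    cf <- summary(fit)$coefficients
    b <- cf[term, 1]; se <- cf[term, 2]; p <- cf[term, 4]
    sep <- abs(b) > 15 || se > 100 || !fit$converged
    data.frame(predictor = term,
               or = if (sep) sign(b) * Inf else exp(b),
               ci_lower = if (sep) NA_real_ else exp(b - 1.96 * se),
               ci_upper = if (sep) NA_real_ else exp(b + 1.96 * se),
               p = p, separation = sep, stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, lapply(candidates, function(v) {
    d <- data.frame(y = as.numeric(y), x = as.numeric(df[[v]]))
    d <- d[stats::complete.cases(d), ]
    fit <- stats::glm(y ~ x, family = stats::binomial(), data = d, control = ctrl)
    r <- wald_row(fit, "x")
    r$predictor <- v
    r
  }))
  uni$included <- !is.na(uni$p) & uni$p < enter_p
  included <- uni$predictor[uni$included]
  multi <- NULL
  if (length(included)) {
    d <- df[, c(outcome, included), drop = FALSE]
    d[] <- lapply(d, as.numeric)
    d <- d[stats::complete.cases(d), ]
    fml <- stats::as.formula(paste(outcome, "~", paste(included, collapse = " + ")))
    fit <- stats::glm(fml, family = stats::binomial(), data = d, control = ctrl)
    multi <- do.call(rbind, lapply(included, function(v) wald_row(fit, v)))
    multi$retained <- !is.na(multi$p) & multi$p < retain_p
  }
  structure(list(univariable = uni, multivariable = multi, included = included,
                 converged = TRUE),
            class = "logistic_screen")
}

#' @export
print.logistic_screen <- function(x, digits = 2, ...) {
  cat("Univariable logistic screening\n")
  u <- x$univariable
  for (i in seq_len(nrow(u)))
    cat(sprintf("  %-14s OR %5.2f (%.2f-%.2f)  p = %.3f%s\n", u$predictor[i],
                u$or[i], u$ci_lower[i], u$ci_upper[i], u$p[i],
                if (u$included[i]) "  *included*" else ""))
  if (is.null(x$multivariable)) {
    cat("Multivariable model: empty (no candidate with p < entry threshold)\n")
  } else {
    cat("Multivariable model\n")
    m <- x$multivariable
    for (i in seq_len(nrow(m)))
      cat(sprintf("  %-14s OR %5.2f (%.2f-%.2f)  p = %.3f%s\n", m$predictor[i],
                  m$or[i], m$ci_lower[i], m$ci_upper[i], m$p[i],
                  if (m$retained[i]) "  *retained*" else ""))
  }
  invisible(x)
}

#' Sample size for a two-sample t-test at unequal allocation
#'
#' Smallest experimental-group size n such that a two-sided two-sample
#' Student t-test with control group of size `ratio * n` reaches the target
#' power for mean difference `delta` at common standard deviation `sd`,
#' computed by iterating the noncentral-t power equation.
#'
#' @param delta true mean difference (nonzero).
#' @param sd common standard deviation (> 0).
#' @param ratio control-to-experimental allocation ratio m (> 0).
#' @param alpha two-sided type-I error level.
#' @param power target power.
#' @return An object of class `sample_size_result`: list with `n`
#'   (experimental group), `n_control`, achieved `power`, and the inputs.
#' @export
sample_size_t <- function(delta, sd, ratio = 1, alpha = 0.05, power = 0.8) {
  if (delta == 0) stop("delta must be nonzero")
  if (sd <= 0) stop("sd must be positive")
  if (ratio <= 0) stop("allocation ratio must be positive")
  pw <- function(n) {
    m <- ratio * n
    df <- n + m - 2
    if (df < 1) return(0)
    ncp <- abs(delta) / (sd * sqrt(1 / n + 1 / m))
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
  # normal-approximation start, then walk to the smallest adequate n
  za <- stats::qnorm(1 - alpha / 2); zb <- stats::qnorm(power)
  n <- max(2, floor(((za + zb) * sd / abs(delta))^2 * (1 + 1 / ratio)) - 2)
  while (pw(n) < power) n <- n + 1
  while (n > 2 && pw(n - 1) >= power) n <- n - 1
  structure(list(n = as.integer(n), n_control = ratio * n, power = pw(n),
                 delta = delta, sd = sd, ratio = ratio, alpha = alpha,
                 target_power = power),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf(paste0("Two-sample t-test sample size: n = %d (experimental), ",
                     "control = %.1f (ratio %.3f)\n"),
              x$n, x$n_control, x$ratio))
  cat(sprintf("  delta %.3g, sd %.3g, alpha %.3g, power %.3f (achieved %.3f)\n",
              x$delta, x$sd, x$alpha, x$target_power, x$power))
  invisible(x)
}
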