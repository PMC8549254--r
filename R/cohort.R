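# Synthetic CRT cohorts.
#
# Two modes.  Exact-count mode lays out binary covariates so that every
# requested 2x2 table against the responder outcome is reproduced exactly
# (which covariate goes to which patient inside a response class is a
# seeded permutation, so margins are exact while the joint structure is
# randomized).  Stochastic mode draws covariates from prevalences and the
# responder outcome from a logistic model with the requested per-covariate
# odds ratios, the intercept solved so the expected responder fraction is
# met.  Continuous measures (AVPD, regional contributions, LVESV and its
# follow-up change) are drawn per response class with means and SDs typical
# of a CRT cohort; the follow-up volume is constructed from the baseline and
# a per-class change that respects the 15%-reduction responder boundary.

# exposed counts c(responders, non-responders) for the default 65-patient
# cohort (37 responders / 28 non-responders)
DEFAULT_EXACT_COUNTS <- list(
  ischemic = c(14, 18),
  lbbb     = c(34, 22),
  qrs150   = c(34, 23),
  male     = c(27, 19),
  lge      = c(23, 17),
  dyssync  = c(15, 12),
  neg_sept = c(16, 12)
)

DEFAULT_PREVALENCE <- c(ischemic = 32 / 65, lbbb = 56 / 65, qrs150 = 57 / 65,
                        male = 46 / 65, lge = 40 / 65, dyssync = 27 / 63,
                        neg_sept = 28 / 65)

# per-response-class c(mean, sd): responders first
DEFAULT_CONTINUOUS <- list(
  avpd_mm     = list(resp = c(8.0, 3.1), non = c(8.8, 3.2)),
  sv_long_pct = list(resp = c(53, 18),  non = c(53, 19)),
  sv_lat_pct  = list(resp = c(38, 15),  non = c(45, 16))
)

#' Specify a synthetic CRT cohort
#'
#' @param n number of patients.
#' @param responders number of responders (exact mode) — or, in stochastic
#'   mode, `responder_fraction` is used instead.
#' @param responder_fraction expected responder fraction (stochastic mode).
#' @param mode `"exact"` (reproduce the count structure exactly) or
#'   `"stochastic"`.
#' @param counts named list of `c(exposed responders, exposed
#'   non-responders)` counts for the binary covariates (exact mode).
#' @param missing named list of `c(responders, non-responders)` counts of
#'   patients with a missing (non-assessable) value per covariate.
#' @param prevalence named covariate prevalences (stochastic mode).
#' @param odds_ratios named covariate-to-outcome odds ratios (stochastic
#'   mode; covariates absent from the vector get OR 1).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 65, responders = 37, responder_fraction = 37 / 65,
                        mode = c("exact", "stochastic"),
                        counts = DEFAULT_EXACT_COUNTS,
                        missing = list(dyssync = c(1, 1)),
                        prevalence = DEFAULT_PREVALENCE,
                        odds_ratios = NULL,
                        seed = 1L) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative")
  if (n == 0L) { responders <- 0L; counts <- list(); missing <- list() }
  if (mode == "exact") {
    if (responders > n) stop("more responders than patients")
    nn <- n - responders
    for (nm in names(counts)) {
      k <- counts[[nm]]
      miss <- if (nm %in% names(missing)) missing[[nm]] else c(0, 0)
      if (length(k) != 2L || any(k < 0) || k[1] + miss[1] > responders ||
          k[2] + miss[2] > nn)
        stop(sprintf("infeasible exact counts for covariate '%s'", nm))
    }
  }
  if (!is.null(responder_fraction) &&
      (responder_fraction < 0 || responder_fraction > 1))
    stop("responder fraction must lie in [0, 1]")
  structure(list(n = n, responders = as.integer(responders),
                 responder_fraction = responder_fraction, mode = mode,
                 counts = counts, missing = missing, prevalence = prevalence,
                 odds_ratios = odds_ratios, seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_columns <- c("id", "sex", "age", "qrs_ms", "lbbb", "ischemic", "dyssync",
                    "lge", "lvesv_base_ml", "lvesv_fu_ml", "avpd_mm",
                    "sv_long_pct", "sv_lat_pct", "sv_sept_pct")

empty_cohort <- function() {
  df <- data.frame(id = character(0), sex = character(0), age = numeric(0),
                   qrs_ms = numeric(0), lbbb = logical(0), ischemic = logical(0),
                   dyssync = logical(0), lge = logical(0),
                   lvesv_base_ml = numeric(0), lvesv_fu_ml = numeric(0),
                   avpd_mm = numeric(0), sv_long_pct = numeric(0),
                   sv_lat_pct = numeric(0), sv_sept_pct = numeric(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Generate a synthetic CRT cohort
#'
#' @param spec a [cohort_spec].
#' @return A `cohort_table` (data frame) with one row per patient and
#'   columns `r paste(cohort_columns, collapse = ", ")`.  The generation
#'   seed is recorded in `attr(, "seed")`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, build_cohort(spec))
}

build_cohort <- function(spec) {
  n <- spec$n
  if (n == 0L) return(empty_cohort())

  if (spec$mode == "exact") {
    responder <- c(rep(TRUE, spec$responders), rep(FALSE, n - spec$responders))
    draw_from <- function(pool, k) pool[sample.int(length(pool), k)]
    flag <- function(nm) {
      k <- spec$counts[[nm]]
      if (is.null(k)) return(rep(FALSE, n))
      f <- rep(FALSE, n)
      f[draw_from(which(responder), k[1])] <- TRUE
      f[draw_from(which(!responder), k[2])] <- TRUE
      miss <- spec$missing[[nm]]
      if (!is.null(miss) && any(miss > 0)) {
        for (cls in 1:2) {
          pool <- which(if (cls == 1) responder & !f else !responder & !f)
          if (miss[cls] > 0) f[draw_from(pool, miss[cls])] <- NA
        }
      }
      f
    }
    cov <- lapply(stats::setNames(nm = names(DEFAULT_EXACT_COUNTS)), flag)
  } else {
    cov <- lapply(stats::setNames(nm = names(DEFAULT_PREVALENCE)), function(nm) {
      p <- if (nm %in% names(spec$prevalence)) as.numeric(spec$prevalence[[nm]]) else 0
      stats::runif(n) < p
    })
    X <- do.call(cbind, lapply(cov, as.numeric))
    lor <- vapply(colnames(X), function(nm) {
      if (nm %in% names(spec$odds_ratios)) log(as.numeric(spec$odds_ratios[[nm]])) else 0
    }, numeric(1))
    lp <- as.numeric(X %*% lor)
    target <- spec$responder_fraction
    b0 <- if (target <= 0) -Inf else if (target >= 1) Inf else
      stats::uniroot(function(b) mean(stats::plogis(b + lp)) - target,
                     c(-20, 20))$root
    responder <- stats::runif(n) < stats::plogis(b0 + lp)
  }

  # continuous measures per response class
  draw2 <- function(par, cls) stats::rnorm(sum(cls), par[1], par[2])
  per_class <- function(name) {
    p <- DEFAULT_CONTINUOUS[[name]]
    out <- numeric(n)
    out[responder] <- draw2(p$resp, responder)
    out[!responder] <- draw2(p$non, !responder)
    out
  }
  avpd <- pmax(per_class("avpd_mm"), 0.5)
  sv_long <- per_class("sv_long_pct")
  sv_lat <- per_class("sv_lat_pct")

  neg <- cov$neg_sept
  neg[is.na(neg)] <- FALSE
  sv_sept <- numeric(n)
  sv_sept[neg] <- -abs(stats::rnorm(sum(neg), 0, 13)) - 0.5
  sv_sept[!neg] <- abs(stats::rnorm(sum(!neg), 0, 11))

  qrs <- numeric(n)
  q150 <- cov$qrs150
  q150[is.na(q150)] <- FALSE
  qrs[q150] <- 150 + abs(stats::rnorm(sum(q150), 0, 18))
  qrs[!q150] <- stats::runif(sum(!q150), 120, 149)

  base <- pmax(stats::rnorm(n, 246, 110), 60)
  delta <- numeric(n)
  delta[responder] <- -15 - abs(stats::rnorm(sum(responder), 0, 20))
  delta[!responder] <- -14.9 + abs(stats::rnorm(sum(!responder), 0, 12))
  fu <- base * (1 + delta / 100)

  df <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    sex = ifelse(!is.na(cov$male) & cov$male, "M", "F"),
    age = round(pmin(pmax(stats::rnorm(n, 67, 9), 35), 90)),
    qrs_ms = round(qrs),
    lbbb = cov$lbbb, ischemic = cov$ischemic, dyssync = cov$dyssync,
    lge = cov$lge,
    lvesv_base_ml = round(base, 1), lvesv_fu_ml = round(fu, 1),
    avpd_mm = round(avpd, 1),
    sv_long_pct = round(sv_long, 1), sv_lat_pct = round(sv_lat, 1),
    sv_sept_pct = round(sv_sept, 1),
    stringsAsFactors = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  attr(df, "seed") <- spec$seed
  attr(df, "mode") <- spec$mode
  df
}

#' Classify CRT response from LVESV change
#'
#' Relative change `100 * (follow-up - baseline) / baseline` in percent
#' (negative = reduction) and the responder flag: a reduction of at least
#' 15% (`delta <= -15`, boundary inclusive) marks a responder.
#'
#' @param baseline,followup LVESV in ml (vectorized).
#' @return Data frame with `delta_lvesv_pct` and `responder`.
#' @export
classify_responder <- function(baseline, followup) {
  if (any(!is.na(baseline) & baseline <= 0))
    stop("baseline LVESV must be positive")
  delta <- 100 * (followup - baseline) / baseline
  data.frame(delta_lvesv_pct = delta, responder = delta <= -15)
}

# Cohort with derived outcome columns appended.
augment_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) {
    cohort$delta_lvesv_pct <- numeric(0)
    cohort$responder <- logical(0)
    return(cohort)
  }
  cls <- classify_responder(cohort$lvesv_base_ml, cohort$lvesv_fu_ml)
  cohort$delta_lvesv_pct <- cls$delta_lvesv_pct
  cohort$responder <- cls$responder
  cohort
}

#' Construct a 2x2 contingency table
#'
#' @param a,b,c_,d counts: exposed with event, exposed without, unexposed
#'   with, unexposed without.
#' @return An object of class `contingency_2x2` (named integer vector).
#' @export
contingency_2x2 <- function(a, b, c_, d) {
  x <- c(a = a, b = b, c = c_, d = d)
  if (any(x < 0) || any(x != round(x))) stop("2x2 counts must be non-negative integers")
  structure(as.integer(x), names = c("a", "b", "c", "d"), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(x, 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"), c("event", "no event")))
  print(m)
  dr <- attr(x, "dropped")
  if (!is.null(dr) && dr > 0) cat(sprintf("(%d record(s) with missing values dropped)\n", dr))
  invisible(x)
}

#' Build a 2x2 table from a cohort
#'
#' Evaluates an exposure predicate and an outcome predicate on every
#' patient; records with a missing value in either are dropped and counted
#' in `attr(, "dropped")`.  The derived columns `delta_lvesv_pct` and
#' `responder` (LVESV reduction >= 15%) are available to both predicates.
#'
#' @param cohort a `cohort_table`.
#' @param exposure one-sided formula, e.g. `~ sv_sept_pct < 0` or `~ lbbb`.
#' @param outcome one-sided formula; default `~ responder`.
#' @return A [contingency_2x2].
#' @export
build_table2x2 <- function(cohort, exposure, outcome = ~responder) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  df <- augment_cohort(cohort)
  ev <- function(f) as.logical(eval(f[[2]], df, environment(f)))
  e <- ev(exposure)
  o <- ev(outcome)
  keep <- !is.na(e) & !is.na(o)
  dropped <- sum(!keep)
  e <- e[keep]; o <- o[keep]
  t <- contingency_2x2(sum(e & o), sum(e & !o), sum(!e & o), sum(!e & !o))
  attr(t, "dropped") <- dropped
  t
}
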