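# Survival machinery shared by all pipeline stages: two-sided logrank,
# optimized-cutoff dichotomization under a minimum-group-size constraint,
# Kaplan-Meier curves, Cox PH, Mann-Whitney association, Bonferroni.

#' Two-sided logrank test for two groups
#'
#' Standard one-degree-of-freedom logrank chi-square from the observed and
#' expected event counts, with the hypergeometric variance. Implemented
#' directly (not via `survival::survdiff`) so the optimized-cutoff scan can
#' call it thousands of times cheaply; agreement with `survdiff` is enforced
#' in the test suite.
#'
#' @param time Follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Logical or two-level vector assigning each subject to a group.
#' @return A list with `statistic` (chi-square), `p` (two-sided), `n1`, `n2`.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(as.factor(group)) == 1L
  assert_that(sum(g) > 0 && sum(!g) > 0, "logrank needs two non-empty groups")
  pre <- logrank_precompute(time, event)
  res <- logrank_core(pre, g)
  list(statistic = res$statistic, p = res$p, n1 = sum(g), n2 = sum(!g))
}

# Precompute the time-ordered risk-set structure once so the statistic for
# any group assignment is O(n) in cheap vector ops. Subjects censored at an
# event time remain at risk for that event (standard convention, matches
# survival::survdiff).
logrank_precompute <- function(time, event) {
  o <- order(time)
  ts <- time[o]; es <- event[o]
  n <- length(ts)
  ut <- unique(ts[es == 1])
  first_idx <- match(ut, ts)                       # first position at risk
  last_idx <- n + 1L - match(ut, rev(ts))          # last position with this time
  ce_all <- cumsum(es)
  di <- ce_all[last_idx] - c(0, ce_all)[first_idx]
  ni <- n - first_idx + 1
  list(order = o, es = es, n = n, first_idx = first_idx,
       last_idx = last_idx, di = di, ni = ni)
}

# g: logical group-1 indicator in original subject order.
logrank_core <- function(pre, g) {
  gs <- as.numeric(g[pre$order])
  suffix1 <- rev(cumsum(rev(gs)))
  n1i <- suffix1[pre$first_idx]
  ce <- cumsum(gs * pre$es)
  d1i <- ce[pre$last_idx] - c(0, ce)[pre$first_idx]
  frac <- n1i / pre$ni
  oe <- sum(d1i - pre$di * frac)
  ok <- pre$ni > 1
  v <- sum((pre$di * frac * (1 - frac) * (pre$ni - pre$di) / (pre$ni - 1))[ok])
  stat <- if (v > 0) oe^2 / v else 0
  p <- if (v > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1
  list(statistic = stat, p = p)
}

# Fast scan core: logrank p for every candidate cutoff of a numeric feature.
# Candidates are midpoints between consecutive sorted distinct values;
# candidates violating the minimum-group-size constraint are inadmissible.
logrank_scan <- function(values, time, event, min_group_frac) {
  n <- length(values)
  uq <- sort(unique(values))
  if (length(uq) < 2) {
    return(tibble(cutoff = numeric(), statistic = numeric(), p = numeric(),
                  n_low = integer(), n_high = integer()))
  }
  cuts <- (uq[-1] + uq[-length(uq)]) / 2
  min_n <- ceiling(min_group_frac * n)
  pre <- logrank_precompute(time, event)
  m <- length(cuts)
  stat <- rep(NA_real_, m); pv <- rep(NA_real_, m); nhi <- integer(m)
  for (i in seq_len(m)) {
    hi <- values > cuts[i]
    n_hi <- sum(hi)
    if (min(n_hi, n - n_hi) < min_n) next
    lr <- logrank_core(pre, hi)
    stat[i] <- lr$statistic; pv[i] <- lr$p; nhi[i] <- n_hi
  }
  keep <- which(!is.na(pv))
  tibble(cutoff = cuts[keep], statistic = stat[keep], p = pv[keep],
         n_low = n - nhi[keep], n_high = nhi[keep])
}

#' Survival-optimized dichotomization of a continuous feature
#'
#' Scans all candidate cutoffs (midpoints between consecutive sorted distinct
#' values), discards candidates leaving fewer than `min_group_frac` of the
#' cohort in either group, and returns the cutoff minimizing the two-sided
#' logrank p-value. Ties in p are broken toward the smallest cutoff so results
#' are reproducible. Note the returned p is a maximally selected statistic and
#' is anti-conservative if read as a fixed-cutoff test.
#'
#' @param values Feature values, one per patient.
#' @param time,event Survival outcome (months; 1 = death observed).
#' @param min_group_frac Minimum fraction of patients required in each group.
#' @param feature Optional feature name carried into the result.
#' @return A list of class `dichotomization` with `feature`, `cutoff`,
#'   `statistic`, `p`, `n_low`, `n_high`, `admissible`, and `group`
#'   (`"low"`/`"high"` per patient; `NA` when inadmissible).
#' @export
optimize_cutoff <- function(values, time, event, min_group_frac = 0.15,
                            feature = "feature") {
  stopifnot(length(values) == length(time), length(time) == length(event))
  scan <- logrank_scan(values, time, event, min_group_frac)
  if (nrow(scan) == 0) {
    return(structure(list(feature = feature, cutoff = NA_real_,
                          statistic = NA_real_, p = NA_real_,
                          n_low = NA_integer_, n_high = NA_integer_,
                          admissible = FALSE,
                          group = rep(NA_character_, length(values)),
                          scan = scan),
                     class = "dichotomization"))
  }
  cand <- which(scan$p == min(scan$p))
  bi <- cand[which.min(scan$cutoff[cand])]  # tie-break: smallest cutoff
  group <- ifelse(values > scan$cutoff[bi], "high", "low")
  structure(list(feature = feature, cutoff = scan$cutoff[bi],
                 statistic = scan$statistic[bi], p = scan$p[bi],
                 n_low = scan$n_low[bi], n_high = scan$n_high[bi],
                 admissible = TRUE, group = group, scan = scan),
            class = "dichotomization")
}

#' @export
print.dichotomization <- function(x, ...) {
  if (x$admissible) {
    cat(sprintf("<dichotomization> %s: cutoff %.4g, logrank p %.3g (n_low %d, n_high %d)\n",
                x$feature, x$cutoff, x$p, x$n_low, x$n_high))
  } else {
    cat(sprintf("<dichotomization> %s: no admissible cutoff\n", x$feature))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dichotomization <- function(x, ...) {
  tibble(feature = x$feature, cutoff = x$cutoff, statistic = x$statistic,
         p = x$p, n_low = x$n_low, n_high = x$n_high,
         admissible = x$admissible)
}

#' @exportS3Method generics::glance
glance.dichotomization <- function(x, ...) tidy(x)

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via [survival::survfit()]; censored subjects leave
#' the risk set without a step.
#'
#' @param time,event Survival outcome.
#' @param group Optional grouping vector; one curve per level.
#' @return A tibble with `time`, `n_risk`, `n_event`, `surv` (and `group`).
#' @export
km_curve <- function(time, event, group = NULL) {
  df <- data.frame(time = time, event = event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
           surv = fit$surv)
  } else {
    df$group <- group
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    strata <- rep(names(fit$strata), fit$strata)
    tibble(group = sub("^group=", "", strata), time = fit$time,
           n_risk = fit$n.risk, n_event = fit$n.event, surv = fit$surv)
  }
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with Efron tie handling via [survival::coxph()].
#'
#' @param data Data frame containing the outcome and covariates.
#' @param covariates Character vector of covariate column names.
#' @param time_col,event_col Outcome column names.
#' @param ties Tie-handling method (`"efron"` default, `"breslow"` available).
#' @return A tibble with one row per model term: `term`, `estimate`
#'   (log-hazard coefficient), `hr`, `p`, `conf_low`, `conf_high` (HR scale),
#'   and a `flag` column noting convergence problems.
#' @export
cox_fit <- function(data, covariates, time_col = "os_months",
                    event_col = "event", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  for (cv in covariates) {
    vals <- data[[cv]]
    assert_that(length(unique(vals[!is.na(vals)])) > 1,
                paste0("constant covariate: ", cv))
  }
  assert_that(nrow(data) > length(covariates),
              "need more subjects than covariates")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- tryCatch(survival::coxph(fml, data = data, ties = ties),
                  warning = function(w) {
                    f <- suppressWarnings(survival::coxph(fml, data = data, ties = ties))
                    attr(f, "radgen_flag") <- conditionMessage(w)
                    f
                  })
  s <- summary(fit)
  ci <- s$conf.int
  tibble(term = rownames(s$coefficients),
         estimate = s$coefficients[, "coef"],
         hr = s$coefficients[, "exp(coef)"],
         p = s$coefficients[, "Pr(>|z|)"],
         conf_low = ci[, "lower .95"],
         conf_high = ci[, "upper .95"],
         flag = attr(fit, "radgen_flag") %||% NA_character_)
}

#' Mann-Whitney U association between a binary state and a feature
#'
#' Two-sided rank-sum test; the exact distribution is used when both groups
#' have at most 8 observations and there are no ties, otherwise the normal
#' approximation with continuity correction.
#'
#' @param state Binary grouping vector (both levels must be present).
#' @param values Feature values.
#' @return A tibble with `u`, `p`, `n1`, `n2`.
#' @export
mw_association <- function(state, values) {
  mw <- mw_stat(state, values)
  tibble(u = mw$u, p = mw$p, n1 = mw$n1, n2 = mw$n2)
}

# list-returning core shared with the association stage (avoids building a
# tibble per pathway x feature pair)
mw_stat <- function(state, values) {
  lv <- unique(state[!is.na(state)])
  assert_that(length(lv) == 2, "state must have exactly two levels present")
  x <- values[state == lv[1]]
  y <- values[state == lv[2]]
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Bonferroni correction
#'
#' `min(1, m * p)` with family size `m = length(p)` by default; the family
#' size is attached so every adjusted p is auditable.
#'
#' @param p Vector of raw p-values.
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values, with attribute `family_size`.
#' @export
bonferroni <- function(p, m = length(p)) {
  out <- pmin(1, m * p)
  attr(out, "family_size") <- m
  out
}
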