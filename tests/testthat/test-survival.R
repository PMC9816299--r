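test_that("logrank matches the hand-computed 6-subject table and survdiff", {
  # A: times 1,2,3 all events; B: 10,20,30 all events.
  # O-E = 0.5+0.6+0.75 = 1.85; V = 0.25+0.24+0.1875 = 0.6775;
  # chi2 = 1.85^2/0.6775 = 5.0517
  lr <- logrank_test(c(1, 2, 3, 10, 20, 30), rep(1, 6),
                     c("A", "A", "A", "B", "B", "B"))
  expect_equal(lr$statistic, 1.85^2 / 0.6775, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(1.85^2 / 0.6775, 1, lower.tail = FALSE))

  set.seed(8)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    t <- round(rexp(n, 0.05), 1)        # rounding forces ties
    e <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(e) == 0) next
    lr <- logrank_test(t, e, g)
    sd_ <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(lr$statistic, unname(sd_$chisq), tolerance = 1e-10)
  }
})

test_that("logrank is symmetric and null on identical groups", {
  t <- c(2, 5, 9, 2, 5, 9); e <- c(1, 1, 0, 1, 1, 0)
  g <- c(1, 1, 1, 2, 2, 2)   # identical composition
  lr <- logrank_test(t, e, g)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)
  set.seed(4)
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.8); g2 <- rbinom(30, 1, 0.5)
  expect_equal(logrank_test(t2, e2, g2)$p, logrank_test(t2, e2, 1 - g2)$p)
})

test_that("optimize_cutoff is the exhaustive admissible scan", {
  set.seed(12)
  for (i in 1:5) {
    n <- 40
    vals <- rnorm(n)
    t <- rexp(n, 0.05); e <- rbinom(n, 1, 0.75)
    oc <- optimize_cutoff(vals, t, e)
    oracle <- naive_best_cutoff(vals, t, e)
    expect_equal(oc$cutoff, oracle$cutoff)
    expect_equal(oc$p, oracle$p, tolerance = 1e-9)
    # no admissible candidate is skipped, minimality holds
    expect_true(all(oc$scan$p >= oc$p - 1e-12))
    expect_gte(min(oc$scan$n_low, oc$scan$n_high), ceiling(0.15 * n))
  }
})

test_that("optimize_cutoff respects group minima and flags degenerate input", {
  coh_t <- rexp(20, 0.04); coh_e <- rbinom(20, 1, 0.8)
  oc <- optimize_cutoff(runif(20), coh_t, coh_e)
  if (oc$admissible) expect_gte(min(oc$n_low, oc$n_high), 3)
  const <- optimize_cutoff(rep(1, 20), coh_t, coh_e)
  expect_false(const$admissible)
  expect_true(is.na(const$cutoff))
})

test_that("optimized cutoff localizes a strong planted hazard step", {
  hits <- vapply(1:4, function(r) {
    set.seed(600 + r)
    n <- 40
    vals <- runif(n, 0, 10)
    hr <- ifelse(vals > 5, 5, 1)
    t <- 30 * (rexp(n) / hr)^(1 / 1.2)
    oc <- optimize_cutoff(vals, t, rep(1, n))
    abs(oc$cutoff - 5) < 1.5
  }, logical(1))
  expect_gte(sum(hits), 3)
})

test_that("Kaplan-Meier equals the hand product-limit estimate", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1 (no event rows at all)
  km2 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # random case vs independent product-limit; non-increasing
  set.seed(5)
  t <- round(rexp(50, 0.1), 1); e <- rbinom(50, 1, 0.6)
  km3 <- km_curve(t, e)
  hk <- hand_km(t, e)
  expect_equal(km3$surv[km3$n_event > 0], hk$surv, tolerance = 1e-12)
  expect_true(all(diff(km3$surv) <= 1e-12))
  # no censoring: last value equals empirical survival fraction (0)
  km4 <- km_curve(t, rep(1, 50))
  expect_equal(min(km4$surv), 0)
})

test_that("Cox fit recovers a planted hazard ratio and rejects constants", {
  set.seed(41)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t <- 30 * (rexp(n) / ifelse(x == 1, 2, 1))^(1 / 1.2)
  cens <- runif(n, 0, 120)
  df <- data.frame(os_months = pmin(t, cens), event = as.integer(t <= cens),
                   marker = x)
  fit <- cox_fit(df, "marker")
  expect_gt(fit$hr, 1.6); expect_lt(fit$hr, 2.5)
  expect_lt(fit$p, 1e-6)
  df$const <- 1
  expect_error(cox_fit(df, c("marker", "const")), "constant")
})

test_that("Mann-Whitney association matches exhaustive enumeration", {
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  mw <- mw_association(rep(c("a", "b"), each = 3), c(x, y))
  expect_equal(mw$p, 0.1)                      # 2/20 orderings as extreme
  expect_equal(mw$p, enumerate_mw_p(x, y))
  expect_true(mw$u %in% c(0, 9))
  # interleaved values: U near n1 n2 / 2, p near 1
  mw2 <- mw_association(rep(c("a", "b"), 4), c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_gt(mw2$p, 0.5)
  # label swap symmetry
  st <- rep(c("a", "b"), each = 5)
  v <- rnorm(10)
  expect_equal(mw_association(st, v)$p,
               mw_association(rev(st), rev(v))$p)
  # enumeration agreement on random small samples without ties
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(5)
    mw3 <- mw_association(rep(c("a", "b"), c(4, 5)), c(x, y))
    expect_equal(mw3$p, enumerate_mw_p(x, y), tolerance = 1e-12)
  }
  expect_error(mw_association(rep("a", 4), rnorm(4)), "two levels")
})

test_that("Bonferroni is min(1, m p) with the family size recorded", {
  out <- bonferroni(rep(0.01, 5))
  expect_equal(as.numeric(out), rep(0.05, 5))
  expect_equal(attr(out, "family_size"), 5)
  expect_equal(as.numeric(bonferroni(0.03)), 0.03)    # m = 1 identity
  p <- runif(10)
  expect_true(all(bonferroni(p) >= p))
  expect_true(all(bonferroni(p) <= 1))
})
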