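# strong-signal classification dataset: three informative features plus noise
make_ml_dataset <- function(n = 200, p_noise = 7, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (3 + p_noise)), nrow = n)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
    score <- rowSums(x[, 1:3])
    y <- as.integer(score + rnorm(n, sd = 0.5) > 0)
    list(features = dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%03d", 1:n)),
      tibble::as_tibble(x)),
      labels = y)
  })
}

test_that("targets use strict thresholds and drop unknowable labels", {
  coh <- tibble::tibble(
    patient_id = paste0("P", 1:6),
    os_months = c(25, 24, 10, 40, 30, 5),
    event = c(1, 1, 0, 0, 1, 1))
  tt <- make_targets(coh, 24)
  lab <- function(id) tt$label[tt$patient_id == id]
  expect_equal(lab("P1"), 1L)   # OS 25 > 24
  expect_equal(lab("P2"), 0L)   # OS 24, death observed
  expect_false("P3" %in% tt$patient_id)  # censored at 10 < 24: unknowable
  expect_equal(lab("P4"), 1L)   # censored after 24: known survivor

  tt2 <- make_targets(coh, NA)
  expect_equal(unique(tt2$threshold), median(coh$os_months))
  expect_equal(unique(tt2$model), "os_gt_median")

  coh2 <- coh; coh2$os_months <- coh2$os_months + 100
  expect_warning(make_targets(coh2, 24), "single-class")
})

test_that("preprocessing standardizes on train and drops redundancy", {
  set.seed(3)
  tr <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  tr <- cbind(tr, f_dup = tr[, 1])               # perfect duplicate
  te <- matrix(rnorm(40) + 5, 8, 5, dimnames = list(NULL, colnames(tr)))
  pp <- preprocess_features(tr, te)
  expect_equal(sort(unique(c(colnames(pp$train)))),
               sort(pp$kept))
  expect_equal(ncol(pp$train), 4)                 # one of the pair dropped
  expect_true(any(c("f1", "f_dup") %in% pp$dropped$redundant))
  expect_equal(unname(colMeans(pp$train)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(pp$train, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # test transformed with train statistics: means stay far from 0
  expect_true(all(colMeans(pp$test) > 2))
  # zero-variance feature dropped with a warning
  tr0 <- cbind(tr, f_const = 1)
  expect_warning(pp0 <- preprocess_features(tr0), "zero-variance")
  expect_false("f_const" %in% pp0$kept)
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  set.seed(8)
  x <- matrix(rnorm(80), 40, 2)
  y <- rep(c(0L, 1L), c(30, 10))
  sm <- smote_oversample(x, y)
  expect_equal(sum(sm$y == 0), sum(sm$y == 1))
  expect_equal(nrow(sm$x), 60)
  # balanced input passes through untouched
  yb <- rep(c(0L, 1L), 20)
  expect_identical(smote_oversample(x, yb)$x, x)
  # synthetic points lie on segments between minority samples
  minx <- x[y == 1, ]
  synth <- sm$x[41:60, , drop = FALSE]
  on_segment <- apply(synth, 1, function(s) {
    ok <- FALSE
    for (i in 1:9) for (j in (i + 1):10) {
      a <- minx[i, ]; b <- minx[j, ]
      cross <- (s[1] - a[1]) * (b[2] - a[2]) - (s[2] - a[2]) * (b[1] - a[1])
      tpar <- if (abs(b[1] - a[1]) > 1e-12) (s[1] - a[1]) / (b[1] - a[1]) else
        (s[2] - a[2]) / (b[2] - a[2])
      if (abs(cross) < 1e-8 && tpar >= -1e-9 && tpar <= 1 + 1e-9) ok <- TRUE
    }
    ok
  })
  expect_true(all(on_segment))
  # minority of one falls back to duplication with a warning
  y1 <- c(rep(0L, 39), 1L)
  expect_warning(sm1 <- smote_oversample(x, y1), "duplicating")
  expect_equal(sum(sm1$y == 1), 39)
})

test_that("the stacked ensemble separates, is seeded, and is null on noise", {
  set.seed(10)
  n <- 60
  x <- rbind(matrix(rnorm(n, -3, 0.5), n / 2, 2),
             matrix(rnorm(n, 3, 0.5), n / 2, 2))
  colnames(x) <- c("a", "b")
  y <- rep(c(0L, 1L), each = n / 2)
  m <- train_ensemble(x, y, seed = 5, n_trees = 20, ga_pop = 8, ga_gens = 3)
  expect_gte(auc_score(y, predict(m, x)), 0.99)
  m2 <- train_ensemble(x, y, seed = 5, n_trees = 20, ga_pop = 8, ga_gens = 3)
  expect_identical(predict(m, x), predict(m2, x))

  # label shuffles: held-out AUC stays in the null band on average
  set.seed(11)
  xs <- matrix(rnorm(70 * 4), 70, 4, dimnames = list(NULL, paste0("v", 1:4)))
  aucs <- vapply(1:12, function(i) {
    ys <- sample(rep(c(0L, 1L), c(35, 35)))
    tr <- 1:50; te <- 51:70
    mm <- train_ensemble(xs[tr, ], ys[tr], seed = i, n_trees = 15,
                         ga_pop = 8, ga_gens = 3)
    auc_score(ys[te], predict(mm, xs[te, ]))
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("Monte Carlo CV is seeded, consistent, and importance sums to 100", {
  ds <- make_ml_dataset(n = 120, seed = 21)
  targets <- tibble::tibble(patient_id = ds$features$patient_id,
                            model = "toy", threshold = 0,
                            label = ds$labels)
  cfg <- radgen_config(seed = 6, n_folds = 6, n_trees = 15, ga_pop = 8,
                       ga_gens = 3)
  cv <- suppress_radgen_warnings(monte_carlo_cv(ds$features, targets, cfg))
  cv2 <- suppress_radgen_warnings(monte_carlo_cv(ds$features, targets, cfg))
  expect_identical(cv$metrics, cv2$metrics)
  expect_equal(nrow(cv$metrics), 6)
  # metrics recompute exactly from the stored confusion counts
  m <- cv$metrics
  expect_equal(m$acc, (m$tp + m$tn) / (m$tp + m$tn + m$fp + m$fn))
  expect_equal(m$sns, m$tp / (m$tp + m$fn))
  expect_equal(m$spc, m$tn / (m$tn + m$fp))
  expect_equal(m$ppv, m$tp / (m$tp + m$fp))
  expect_equal(m$npv, m$tn / (m$tn + m$fn))
  # normalized importance sums to 100 per model
  expect_equal(sum(cv$importance$importance), 100, tolerance = 1e-9)
  # informative features outrank the pure-noise features
  top3 <- head(cv$importance$feature, 3)
  expect_true(all(top3 %in% c("x1", "x2", "x3")))
})

test_that("a feature identical to the target dominates the R2 ranking", {
  set.seed(2)
  y <- rbinom(60, 1, 0.5)
  x <- cbind(identical = y, noise = rnorm(60))
  imp <- radgen:::r2_importance(x, y)
  expect_equal(unname(imp["identical"]), 1)
  expect_lt(unname(imp["noise"]), 0.2)
})
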