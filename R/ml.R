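# Cross-validated prognostic classification. Targets are dichotomized
# overall survival (> 24 months, > cohort median, > 36 months); patients
# censored before a threshold are excluded from that model (their label is
# unknowable). Preprocessing (standardization, redundancy removal) and SMOTE
# oversampling are fit on each training split only. The classifier is a
# stacked ensemble of a bagged random forest, an RBF-kernel ridge classifier,
# and a Gaussian naive Bayes wrapped in a genetic feature-subset selector
# (the latter substitutes a proprietary "multi-Gaussian genetic algorithm"
# of the original protocol), combined by a logistic meta-learner fitted on
# out-of-fold base probabilities.

#' Binary survival targets
#'
#' Builds one binary label set per threshold: label 1 iff OS strictly exceeds
#' the threshold. `NA` thresholds mean the cohort median OS. Patients
#' censored before the threshold are excluded from that model's dataset.
#'
#' @param cohort Cohort tibble (`patient_id`, `os_months`, `event`).
#' @param thresholds_months Numeric thresholds; `NA` = cohort median.
#' @return A tibble `patient_id`, `model` (e.g. `"os_gt_24"`), `threshold`,
#'   `label` (0/1; excluded patients are absent).
#' @export
make_targets <- function(cohort, thresholds_months = c(24, NA, 36)) {
  med <- median(cohort$os_months)
  out <- map(thresholds_months, function(th) {
    is_med <- is.na(th)
    if (is_med) th <- med
    name <- if (is_med) "os_gt_median" else paste0("os_gt_", format(th))
    lab <- ifelse(cohort$os_months > th, 1L,
                  ifelse(cohort$event == 1, 0L, NA_integer_))
    keep <- !is.na(lab)
    tibble(patient_id = cohort$patient_id[keep], model = name,
           threshold = th, label = lab[keep])
  })
  out <- bind_rows(out)
  degen <- out |> group_by(.data$model) |>
    summarise(one_class = dplyr::n_distinct(.data$label) < 2, .groups = "drop")
  if (any(degen$one_class)) {
    warn(paste0("single-class target(s) skipped: ",
                paste(degen$model[degen$one_class], collapse = ", ")))
    out <- out[!out$model %in% degen$model[degen$one_class], ]
  }
  out
}

#' Training-split preprocessing
#'
#' Standardizes features with training mean/SD (zero-SD features are dropped
#' with a warning) and removes redundant features: from every pair with
#' |Spearman| > 0.9 on the training split, the member with the larger mean
#' absolute correlation to all other features is dropped. Test data are
#' transformed with the training parameters only.
#'
#' @param train,test Numeric feature matrices (same columns).
#' @param redundancy_cut Absolute Spearman threshold.
#' @return List `train`, `test`, `dropped` (named by reason), `center`,
#'   `scale`, `kept`.
#' @export
preprocess_features <- function(train, test = NULL, redundancy_cut = 0.9) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  zero_sd <- names(scl)[scl == 0 | is.na(scl)]
  if (length(zero_sd) > 0) warn(paste0("dropping zero-variance feature(s): ",
                                       paste(zero_sd, collapse = ", ")))
  keep <- setdiff(colnames(train), zero_sd)
  tr <- scale(train[, keep, drop = FALSE], center = ctr[keep],
              scale = scl[keep])
  dropped_red <- character(0)
  if (length(keep) > 1) {
    rho <- suppressWarnings(cor(tr, method = "spearman"))
    repeat {
      diag(rho) <- 0
      mx <- which(abs(rho) == max(abs(rho)), arr.ind = TRUE)[1, ]
      if (abs(rho[mx[1], mx[2]]) <= redundancy_cut) break
      mean_abs <- rowMeans(abs(rho))
      drop_i <- if (mean_abs[mx[1]] >= mean_abs[mx[2]]) mx[1] else mx[2]
      dropped_red <- c(dropped_red, colnames(rho)[drop_i])
      rho <- rho[-drop_i, -drop_i, drop = FALSE]
      if (nrow(rho) < 2) break
    }
    keep <- setdiff(keep, dropped_red)
    tr <- tr[, keep, drop = FALSE]
  }
  te <- NULL
  if (!is.null(test)) {
    te <- scale(as.matrix(test)[, keep, drop = FALSE], center = ctr[keep],
                scale = scl[keep])
  }
  list(train = tr, test = te,
       dropped = list(zero_sd = zero_sd, redundant = dropped_red),
       center = ctr[keep], scale = scl[keep], kept = keep)
}

#' SMOTE oversampling
#'
#' Balances the training classes by interpolating synthetic minority samples
#' on segments between a minority sample and one of its k nearest minority
#' neighbours (k = 5, reduced when the minority class is smaller). Falls back
#' to random duplication for a minority class of one. Applied to training
#' data only.
#'
#' @param x Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param k Number of neighbours.
#' @return List `x`, `y` with equal class counts.
#' @export
smote_oversample <- function(x, y, k = 5) {
  x <- as.matrix(x)
  tab <- table(factor(y, levels = c(0, 1)))
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  min_class <- as.integer(names(tab)[which.min(tab)])
  n_needed <- abs(diff(as.integer(tab)))
  minx <- x[y == min_class, , drop = FALSE]
  nmin <- nrow(minx)
  if (nmin == 1) {
    warn("minority class of one; duplicating instead of SMOTE")
    synth <- minx[rep(1, n_needed), , drop = FALSE]
  } else {
    kk <- min(k, nmin - 1)
    d <- as.matrix(stats::dist(minx))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(kk)])
    nn <- matrix(nn, ncol = nmin)  # kk x nmin
    base_i <- sample.int(nmin, n_needed, replace = TRUE)
    nb_i <- vapply(base_i, function(i) nn[sample.int(kk, 1), i], integer(1))
    gap <- runif(n_needed)
    synth <- minx[base_i, , drop = FALSE] +
      gap * (minx[nb_i, , drop = FALSE] - minx[base_i, , drop = FALSE])
  }
  list(x = rbind(x, synth), y = c(y, rep(min_class, n_needed)))
}

# ---- base learners -------------------------------------------------------

# CART: gini-impurity binary tree on a numeric matrix; returns nested list.
fit_tree <- function(x, y, depth = 4, min_n = 5, mtry = ncol(x)) {
  n <- length(y)
  prob <- mean(y)
  if (depth == 0 || n < min_n || prob == 0 || prob == 1) {
    return(list(leaf = TRUE, prob = prob))
  }
  feats <- sample.int(ncol(x), min(mtry, ncol(x)))
  best <- NULL; best_cost <- Inf
  for (fi in feats) {
    xv <- x[, fi]
    o <- order(xv)
    xs <- xv[o]; ys <- y[o]
    cum1 <- cumsum(ys)
    ks <- which(xs[-n] < xs[-1])
    if (length(ks) == 0) next
    nl <- ks; nr <- n - ks
    p1l <- cum1[ks] / nl; p1r <- (cum1[n] - cum1[ks]) / nr
    cost <- (nl * 2 * p1l * (1 - p1l) + nr * 2 * p1r * (1 - p1r)) / n
    j <- which.min(cost)
    if (cost[j] < best_cost) {
      best_cost <- cost[j]
      best <- list(feature = fi, cut = (xs[ks[j]] + xs[ks[j] + 1]) / 2)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = prob))
  go_l <- x[, best$feature] <= best$cut
  list(leaf = FALSE, feature = best$feature, cut = best$cut,
       left = fit_tree(x[go_l, , drop = FALSE], y[go_l], depth - 1, min_n, mtry),
       right = fit_tree(x[!go_l, , drop = FALSE], y[!go_l], depth - 1, min_n, mtry))
}

predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) { out[idx] <<- node$prob; return() }
    go_l <- x[idx, node$feature] <= node$cut
    rec(node$left, idx[go_l])
    rec(node$right, idx[!go_l])
  }
  rec(tree, seq_len(nrow(x)))
  out
}

fit_forest <- function(x, y, n_trees = 50, depth = 5) {
  mtry <- max(1, floor(sqrt(ncol(x))))
  trees <- map(seq_len(n_trees), function(i) {
    bi <- sample.int(length(y), replace = TRUE)
    fit_tree(x[bi, , drop = FALSE], y[bi], depth = depth, mtry = mtry)
  })
  structure(list(trees = trees), class = "radgen_forest")
}

predict_forest <- function(model, x) {
  rowMeans(vapply(model$trees, predict_tree, numeric(nrow(x)), x = x))
}

# RBF kernel ridge classifier: least-squares fit of centred labels in the
# kernel feature space; bandwidth by the median-distance heuristic.
fit_krr <- function(x, y, lambda = 0.5) {
  d2 <- as.matrix(stats::dist(x))^2
  sigma2 <- median(d2[upper.tri(d2)])
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  K <- exp(-d2 / (2 * sigma2))
  alpha <- solve(K + lambda * diag(nrow(K)), y - mean(y))
  structure(list(x = x, alpha = alpha, sigma2 = sigma2, intercept = mean(y)),
            class = "radgen_krr")
}

predict_krr <- function(model, x) {
  cross <- outer(rowSums(x^2), rowSums(model$x^2), `+`) -
    2 * x %*% t(model$x)
  K <- exp(-cross / (2 * model$sigma2))
  p <- model$intercept + as.numeric(K %*% model$alpha)
  pmin(pmax(p, 0.001), 0.999)
}

# Gaussian naive Bayes on a feature subset.
fit_gnb <- function(x, y, subset = seq_len(ncol(x))) {
  xs <- x[, subset, drop = FALSE]
  stats_for <- function(cls) {
    xx <- xs[y == cls, , drop = FALSE]
    list(mu = colMeans(xx), sd = pmax(apply(xx, 2, sd), 1e-3))
  }
  structure(list(subset = subset, prior1 = mean(y),
                 s0 = stats_for(0), s1 = stats_for(1)),
            class = "radgen_gnb")
}

predict_gnb <- function(model, x) {
  xs <- x[, model$subset, drop = FALSE]
  ll <- function(s) {
    rowSums(sweep(sweep(xs, 2, s$mu, `-`)^2, 2, -2 * s$sd^2, `/`) -
              rep(log(s$sd), each = nrow(xs)))
  }
  l1 <- ll(model$s1) + log(max(model$prior1, 1e-9))
  l0 <- ll(model$s0) + log(max(1 - model$prior1, 1e-9))
  1 / (1 + exp(pmin(pmax(l0 - l1, -30), 30)))
}

# Genetic feature-subset selector around Gaussian naive Bayes: binary
# chromosomes, tournament selection, uniform crossover, bit-flip mutation,
# AUC fitness on an inner 70:30 split.
fit_ga_gnb <- function(x, y, pop_size = 20, generations = 10) {
  p <- ncol(x)
  n <- length(y)
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  tr_i <- c(sample(idx1, max(1, floor(0.7 * length(idx1)))),
            sample(idx0, max(1, floor(0.7 * length(idx0)))))
  te_i <- setdiff(seq_len(n), tr_i)
  if (length(unique(y[te_i])) < 2) { tr_i <- seq_len(n); te_i <- seq_len(n) }
  fitness <- function(chrom) {
    if (!any(chrom)) return(0)
    m <- fit_gnb(x[tr_i, , drop = FALSE], y[tr_i], which(chrom))
    auc_score(y[te_i], predict_gnb(m, x[te_i, , drop = FALSE]))
  }
  pop <- map(seq_len(pop_size), function(i) runif(p) < 0.5)
  fit <- map_dbl(pop, fitness)
  for (g in seq_len(generations)) {
    newpop <- list(pop[[which.max(fit)]])  # elitism
    while (length(newpop) < pop_size) {
      pick <- function() {
        c2 <- sample.int(pop_size, 2)
        pop[[c2[which.max(fit[c2])]]]
      }
      pa <- pick(); pb <- pick()
      child <- ifelse(runif(p) < 0.5, pa, pb)
      child <- xor(child, runif(p) < 1 / p)
      newpop[[length(newpop) + 1]] <- child
    }
    pop <- newpop
    fit <- map_dbl(pop, fitness)
  }
  best <- pop[[which.max(fit)]]
  if (!any(best)) best[sample.int(p, 1)] <- TRUE
  fit_gnb(x, y, which(best))
}

#' Train the stacked ensemble
#'
#' Base learners: bagged random forest (hand-rolled CART trees with feature
#' subsampling), RBF-kernel ridge classifier, and Gaussian naive Bayes with
#' a genetic feature-subset selector. A logistic meta-learner is fitted on
#' 5-fold out-of-fold base probabilities, then the base learners are refitted
#' on the full training data.
#'
#' @param x Preprocessed (standardized) training matrix.
#' @param y Binary labels (0/1).
#' @param seed RNG seed (fixed seed => identical model).
#' @param n_trees,ga_pop,ga_gens Ensemble settings.
#' @return A model of class `radgen_ensemble` with a [predict()] method
#'   returning probabilities.
#' @export
train_ensemble <- function(x, y, seed = 1L, n_trees = 50, ga_pop = 20,
                           ga_gens = 10) {
  x <- as.matrix(x)
  assert_that(length(unique(y)) == 2 && nrow(x) >= 6,
              "degenerate training set")
  with_seed(seed, {
    n <- length(y)
    folds <- sample(rep(1:5, length.out = n))
    oof <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("rf", "krr", "gnb")))
    for (f in 1:5) {
      tr <- folds != f; te <- !tr
      if (sum(te) == 0 || length(unique(y[tr])) < 2) next
      rf <- fit_forest(x[tr, , drop = FALSE], y[tr], n_trees = n_trees)
      kr <- fit_krr(x[tr, , drop = FALSE], y[tr])
      nb <- fit_gnb(x[tr, , drop = FALSE], y[tr])
      oof[te, "rf"] <- predict_forest(rf, x[te, , drop = FALSE])
      oof[te, "krr"] <- predict_krr(kr, x[te, , drop = FALSE])
      oof[te, "gnb"] <- predict_gnb(nb, x[te, , drop = FALSE])
    }
    ok <- complete.cases(oof)
    meta_df <- data.frame(y = y[ok], oof[ok, , drop = FALSE])
    meta <- suppressWarnings(glm(y ~ ., data = meta_df, family = binomial()))
    base <- list(
      rf = fit_forest(x, y, n_trees = n_trees),
      krr = fit_krr(x, y),
      gnb = fit_ga_gnb(x, y, pop_size = ga_pop, generations = ga_gens))
    structure(list(base = base, meta = meta), class = "radgen_ensemble")
  })
}

#' @export
predict.radgen_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  bp <- data.frame(
    rf = predict_forest(object$base$rf, newdata),
    krr = predict_krr(object$base$krr, newdata),
    gnb = predict_gnb(object$base$gnb, newdata))
  as.numeric(predict(object$meta, newdata = bp, type = "response"))
}

# ---- metrics -------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; ties get half credit.
#'
#' @param y Binary labels.
#' @param prob Predicted probabilities/scores.
#' @return AUC in \[0,1\].
#' @export
auc_score <- function(y, prob) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(y, prob, threshold = 0.5) {
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         auc = auc_score(y, prob),
         acc = (tp + tn) / length(y),
         sns = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         spc = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

# per-feature R^2 of the binary label (squared point-biserial correlation)
r2_importance <- function(x, y) {
  apply(as.matrix(x), 2, function(col) {
    if (sd(col) == 0) return(0)
    suppressWarnings(cor(col, y))^2
  })
}

#' Monte Carlo cross-validation
#'
#' Stratified random 80:20 splits (default 100); preprocessing and SMOTE are
#' refitted on every training split; test metrics (AUC, ACC, SNS, SPC, PPV,
#' NPV at probability 0.5) and training-split R-squared feature importances
#' are recorded per fold. Folds whose test split is single-class are redrawn
#' (logged). Importances are averaged over folds and normalized to sum 100
#' per model.
#'
#' @param features Tibble with `patient_id` and feature columns.
#' @param targets Target tibble from [make_targets()] (may contain several
#'   models).
#' @param config A [radgen_config()] (folds, split ratio, ensemble settings,
#'   seed).
#' @return An object of class `cv_result`: `metrics` (per model x fold),
#'   `summary` (per-model means), `importance` (per model x feature,
#'   normalized to 100).
#' @export
monte_carlo_cv <- function(features, targets, config = radgen_config()) {
  models <- unique(targets$model)
  all_metrics <- list(); all_imp <- list()
  for (mod in models) {
    tt <- targets[targets$model == mod, ]
    dat <- inner_join(tt, features, by = "patient_id")
    y <- dat$label
    xmat <- as.matrix(dat[, setdiff(names(features), "patient_id")])
    n <- length(y)
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    n_te1 <- max(1, round((1 - config$train_frac) * length(idx1)))
    n_te0 <- max(1, round((1 - config$train_frac) * length(idx0)))
    fold_rows <- list(); imp_rows <- list()
    redraws <- 0
    for (f in seq_len(config$n_folds)) {
      fold_seed <- derive_seed(config$seed, paste0(mod, "_fold", f))
      res <- with_seed(fold_seed, {
        te <- c(sample(idx1, n_te1), sample(idx0, n_te0))
        tr <- setdiff(seq_len(n), te)
        if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
          redraws <- redraws + 1
          te <- c(sample(idx1, max(1, n_te1)), sample(idx0, max(1, n_te0)))
          tr <- setdiff(seq_len(n), te)
        }
        pp <- suppressWarnings(
          preprocess_features(xmat[tr, , drop = FALSE],
                              xmat[te, , drop = FALSE]))
        imp <- r2_importance(pp$train, y[tr])
        sm <- smote_oversample(pp$train, y[tr])
        model <- train_ensemble(sm$x, sm$y,
                                seed = derive_seed(fold_seed, "ens"),
                                n_trees = config$n_trees,
                                ga_pop = config$ga_pop,
                                ga_gens = config$ga_gens)
        prob <- predict(model, pp$test)
        list(metrics = bind_cols(tibble(model = mod, fold = f),
                                 confusion_metrics(y[te], prob)),
             imp = tibble(model = mod, fold = f,
                          feature = names(imp), r2 = unname(imp)))
      })
      fold_rows[[f]] <- res$metrics
      imp_rows[[f]] <- res$imp
    }
    all_metrics[[mod]] <- bind_rows(fold_rows)
    all_imp[[mod]] <- bind_rows(imp_rows)
  }
  metrics <- bind_rows(all_metrics)
  imp_raw <- bind_rows(all_imp)
  importance <- imp_raw |>
    group_by(.data$model, .data$feature) |>
    summarise(mean_r2 = mean(.data$r2), .groups = "drop_last") |>
    mutate(importance = 100 * .data$mean_r2 / sum(.data$mean_r2)) |>
    ungroup() |>
    arrange(.data$model, dplyr::desc(.data$importance))
  summary <- metrics |>
    group_by(.data$model) |>
    summarise(across(c("auc", "acc", "sns", "spc", "ppv", "npv"),
                     ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  structure(list(metrics = metrics, summary = summary,
                 importance = importance), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) x$summary
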