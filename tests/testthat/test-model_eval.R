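test_that("confusion-matrix metrics match their closed forms", {
  m <- compute_metrics(list(tp = 50, tn = 50, fp = 50, fn = 50))
  expect_equal(m$sn, 0.5); expect_equal(m$sp, 0.5)
  expect_equal(m$bacc, 0.5); expect_equal(m$mcc, 0)

  p <- compute_metrics(list(tp = 100, tn = 100, fp = 0, fn = 0))
  expect_equal(p$sn, 1); expect_equal(p$sp, 1)
  expect_equal(p$bacc, 1); expect_equal(p$mcc, 1)

  w <- compute_metrics(list(tp = 8, tn = 6, fp = 4, fn = 2))
  expect_equal(w$sn, 0.8); expect_equal(w$sp, 0.6)
  expect_equal(w$bacc, 0.7)
  expect_equal(w$mcc, (8 * 6 - 4 * 2) / sqrt(12 * 10 * 10 * 8))

  expect_warning(z <- compute_metrics(list(tp = 0, tn = 5, fp = 0, fn = 5)),
                 "MCC")
  expect_equal(z$mcc, 0)
  expect_error(compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "no evaluated samples")
})

test_that("BACC always equals (Sn + Sp)/2", {
  set.seed(99)
  for (i in 1:50) {
    cm <- as.list(setNames(sample(0:30, 4, replace = TRUE) + 1,
                           c("tp", "tn", "fp", "fn")))
    m <- compute_metrics(cm)
    expect_identical(m$bacc, (m$sn + m$sp) / 2)
  }
})

test_that("rank-statistic AUC matches worked examples and pair counting", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.7, 0.2), c(1, 0, 1, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)  # all ties
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(7)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)                  # rounding forces ties
    expect_equal(roc_auc(s, y), auc_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- sample(0:1, 80, replace = TRUE, prob = c(0.4, 0.6))
  s <- runif(80) + 0.5 * y
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("random forest separates separable data and is seed-deterministic", {
  set.seed(31)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4); X[, 1] <- X[, 1] + 3 * y
  colnames(X) <- paste0("f", 1:4)
  tr <- rf_trainer(ntree = 100)
  fit <- tr$fit(X, y, seed = 5)
  p <- tr$predict_prob(fit, X)
  m <- compute_metrics(confusion_counts(y, as.integer(p >= 0.5)))
  expect_equal(m$bacc, 1)

  fit2 <- tr$fit(X, y, seed = 5)
  expect_identical(p, tr$predict_prob(fit2, X))
  expect_error(tr$fit(X, rep(1L, n), seed = 1), "one class")
})

test_that("stratified CV pools out-of-fold predictions without leakage", {
  set.seed(41)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6); X[, 1:2] <- X[, 1:2] + 1.5 * y
  colnames(X) <- paste0("f", 1:6)
  rep_off <- cross_validate(X, y, folds = 5, trainer = rf_trainer(ntree = 100),
                            seed = 3)
  expect_s3_class(rep_off, "evaluation_report")
  expect_equal(rep_off$tp + rep_off$tn + rep_off$fp + rep_off$fn, n)
  expect_length(rep_off$per_fold, 5L)
  expect_gt(rep_off$bacc, 0.7)

  # resampling changes training folds only: still exactly n out-of-fold
  # scores, one per original sample, and identical fold membership
  rep_on <- cross_validate(X, y, folds = 5, trainer = rf_trainer(ntree = 100),
                           seed = 3, resample = TRUE)
  expect_equal(rep_on$tp + rep_on$tn + rep_on$fp + rep_on$fn, n)
  expect_length(rep_on$scores, n)

  sub <- c(1:6, 101:106)               # 6 per class, fewer than 10 folds
  expect_error(cross_validate(X[sub, ], y[sub], folds = 10),
               "fewer folds")
})

test_that("CV fold sizes follow stratification arithmetic at benchmark scale", {
  y <- c(rep(1L, 470), rep(0L, 318))
  fold_of <- pepTTCA:::.stratified_folds(y, 10L, seed = 2)
  for (f in 1:10) {
    expect_true(sum(y == 1L & fold_of == f) %in% 47:48)
    expect_true(sum(y == 0L & fold_of == f) %in% 31:32)
  }
})

test_that("label-permuted data yields chance-level CV BACC", {
  set.seed(55)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- sample(rep(c(0L, 1L), each = n / 2))
  baccs <- vapply(1:5, function(s)
    cross_validate(X, y, folds = 5, trainer = rf_trainer(ntree = 60),
                   seed = s)$bacc, numeric(1))
  expect_lt(abs(mean(baccs) - 0.5), 0.08)
})

test_that("grid search is exhaustive, deterministic and prefers stronger settings", {
  set.seed(61)
  n <- 150
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5); X[, 1] <- X[, 1] + 1.2 * y
  colnames(X) <- paste0("f", 1:5)

  singleton <- data.frame(ntree = 100L, mtry = "sqrt", nodesize = 1L,
                          stringsAsFactors = FALSE)
  gs1 <- grid_search(X, y, grid = singleton, folds = 4, seed = 2)
  expect_equal(gs1$best$ntree, 100L)

  grid <- data.frame(ntree = c(1L, 200L), mtry = "sqrt", nodesize = 1L,
                     stringsAsFactors = FALSE)
  gs <- grid_search(X, y, grid = grid, folds = 4, seed = 2)
  expect_equal(gs$best$ntree, 200L)
  gs_again <- grid_search(X, y, grid = grid, folds = 4, seed = 2)
  expect_identical(gs$scores, gs_again$scores)
  expect_error(grid_search(X, y, grid = grid[0, ], folds = 4), "empty")
})

test_that("peer trainers run behind the common interface", {
  set.seed(71)
  n <- 100
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3); X[, 1] <- X[, 1] + 2 * y
  colnames(X) <- paste0("f", 1:3)
  for (tr in list(logistic_trainer(), svm_trainer())) {
    fit <- tr$fit(X, y, seed = 1)
    p <- tr$predict_prob(fit, X)
    expect_length(p, n)
    expect_gt(roc_auc(p, y), 0.9)
  }
})
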