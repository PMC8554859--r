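#' Confusion counts from truth and predicted labels
#'
#' @param truth,pred binary 0/1 vectors of equal length.
#' @return named list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  list(tp = sum(truth == 1L & pred == 1L),
       tn = sum(truth == 0L & pred == 0L),
       fp = sum(truth == 0L & pred == 1L),
       fn = sum(truth == 1L & pred == 0L))
}

#' Threshold-based classification metrics
#'
#' Sensitivity (TPR), specificity (TNR), balanced accuracy
#' BACC = (Sn + Sp)/2 and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' When any MCC denominator factor is zero, MCC is 0 by convention (with
#' a warning).
#'
#' @param counts a list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @return named list `sn`, `sp`, `bacc`, `mcc` plus the counts.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n == 0L) stop("no evaluated samples")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) {
    warning("MCC denominator is zero; returning 0 by convention")
    0
  } else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  }
  list(sn = sn, sp = sp, bacc = (sn + sp) / 2, mcc = mcc,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' ROC AUC via the rank statistic
#'
#' Equals the probability that a uniformly chosen positive sample
#' outscores a uniformly chosen negative one, ties counting 1/2
#' (Wilcoxon-Mann-Whitney formulation).
#'
#' @param scores numeric per-sample scores (higher = more positive).
#' @param y binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)                         # mean ranks handle ties as 1/2
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Random-forest trainer specification
#'
#' Wraps `randomForest::randomForest` behind the common trainer interface
#' used by [cross_validate()], [ifs_search()] and [grid_search()]: a list
#' with `fit(X, y, seed)` returning a fitted model and
#' `predict_prob(model, X)` returning positive-class probabilities.
#'
#' @param ntree number of trees.
#' @param mtry variables tried per split: `"sqrt"`, `"log2"` or an integer.
#' @param nodesize minimum terminal-node size.
#' @return a `trainer` object.
#' @export
rf_trainer <- function(ntree = 500L, mtry = "sqrt", nodesize = 1L) {
  structure(list(
    name = sprintf("rf(ntree=%s,mtry=%s,nodesize=%s)", ntree, mtry, nodesize),
    fit = function(X, y, seed = 1L) {
      if (length(unique(y)) < 2L) stop("training labels contain one class")
      m <- if (identical(mtry, "sqrt")) max(1L, floor(sqrt(ncol(X))))
      else if (identical(mtry, "log2")) max(1L, floor(log2(ncol(X))))
      else as.integer(mtry)
      set.seed(seed)
      randomForest::randomForest(
        x = X, y = factor(y, levels = c(0L, 1L)),
        ntree = ntree, mtry = min(m, ncol(X)), nodesize = nodesize)
    },
    predict_prob = function(model, X)
      unname(predict(model, X, type = "prob")[, "1"])
  ), class = "trainer")
}

#' Logistic-regression trainer (peer classifier)
#'
#' @return a `trainer` object (see [rf_trainer()]).
#' @export
logistic_trainer <- function() {
  structure(list(
    name = "logistic",
    fit = function(X, y, seed = 1L) {
      df <- data.frame(.y = y, X, check.names = TRUE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = "binomial"))
    },
    predict_prob = function(model, X) {
      df <- data.frame(X, check.names = TRUE)
      unname(predict(model, newdata = df, type = "response"))
    }
  ), class = "trainer")
}

#' Support-vector-machine trainer (peer classifier)
#'
#' Radial-kernel SVM via e1071 with probability estimates.
#'
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses 1/ncol(X)).
#' @return a `trainer` object (see [rf_trainer()]).
#' @export
svm_trainer <- function(cost = 1, gamma = NULL) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("svm_trainer requires the e1071 package")
  structure(list(
    name = sprintf("svm(cost=%s)", cost),
    fit = function(X, y, seed = 1L) {
      set.seed(seed)
      e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)), cost = cost,
                 gamma = if (is.null(gamma)) 1 / ncol(X) else gamma,
                 probability = TRUE)
    },
    predict_prob = function(model, X) {
      p <- attr(predict(model, X, probability = TRUE), "probabilities")
      unname(p[, "1"])
    }
  ), class = "trainer")
}

.stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold_of <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class and deterministic given the seed. With
#' `resample = TRUE`, SMOTE-Tomek is fit inside each training fold only;
#' test folds are never touched, so no synthetic sample is ever scored
#' and the union of test folds is exactly the original sample set.
#' `resample_before_cv = TRUE` instead rebalances once before splitting
#' (a protocol some studies use; it leaks synthetic information across
#' folds and typically inflates scores — off by default).
#'
#' Headline metrics are computed from the pooled out-of-fold confusion
#' counts and scores (micro aggregation); per-fold reports are retained
#' in `per_fold` and their means in `macro`.
#'
#' @param X feature matrix; rows are samples.
#' @param y binary 0/1 labels.
#' @param folds number of folds (>= 2).
#' @param trainer a `trainer` (default [rf_trainer()]).
#' @param seed integer seed controlling folds, resampling and the
#'   classifier.
#' @param resample apply SMOTE-Tomek within each training fold.
#' @param resample_before_cv rebalance the full matrix before splitting.
#' @param k_neighbors SMOTE neighborhood size.
#' @param threshold decision cutoff on the positive-class probability.
#' @return object of class `evaluation_report`: list with `sn`, `sp`,
#'   `bacc`, `mcc`, `auc`, counts, `per_fold`, `macro`.
#' @export
cross_validate <- function(X, y, folds = 10L, trainer = rf_trainer(),
                           seed = 1L, resample = FALSE,
                           resample_before_cv = FALSE, k_neighbors = 5L,
                           threshold = 0.5) {
  y <- as.integer(y)
  if (folds < 2L) stop("folds must be >= 2")
  if (min(table(y)) < folds)
    stop("a class has fewer samples than folds; use fewer folds")
  if (resample_before_cv) {
    res <- smote_tomek(X, y, k_neighbors = k_neighbors, seed = seed)
    X <- res$X_out; y <- res$y_out
  }
  fold_of <- .stratified_folds(y, folds, seed)
  scores <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (resample && !resample_before_cv) {
      res <- smote_tomek(Xtr, ytr, k_neighbors = k_neighbors,
                         seed = seed + f)
      Xtr <- res$X_out; ytr <- res$y_out
    }
    model <- trainer$fit(Xtr, ytr, seed = seed + f)
    p <- trainer$predict_prob(model, X[te, , drop = FALSE])
    scores[te] <- p
    cm <- confusion_counts(y[te], as.integer(p >= threshold))
    per_fold[[f]] <- c(compute_metrics(cm),
                       list(auc = roc_auc(p, y[te]), fold = f))
  }
  pooled <- compute_metrics(confusion_counts(y, as.integer(scores >= threshold)))
  macro <- list(bacc = mean(vapply(per_fold, `[[`, 0, "bacc")),
                auc = mean(vapply(per_fold, `[[`, 0, "auc")))
  structure(c(pooled,
              list(auc = roc_auc(scores, y), scores = scores,
                   per_fold = per_fold, macro = macro, folds = folds,
                   seed = seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Sn = %.4f  Sp = %.4f  BACC = %.4f  MCC = %.4f  AUC = %.4f\n",
    x$sn, x$sp, x$bacc, x$mcc, x$auc))
  invisible(x)
}

#' Exhaustive grid search over classifier hyperparameters
#'
#' Every grid row is scored by [cross_validate()] BACC; ties go to the
#' earlier row (documented grid order).
#'
#' @param X,y data.
#' @param grid data.frame of hyperparameter combinations; columns are
#'   passed to `make_trainer`.
#' @param make_trainer function(row) -> trainer; default builds
#'   [rf_trainer()] from columns `ntree`, `mtry`, `nodesize`.
#' @param folds,seed,resample passed to [cross_validate()].
#' @return list with `best` (grid row), `best_bacc`, `scores` (per-row
#'   BACC).
#' @export
grid_search <- function(X, y, grid = rf_default_grid(),
                        make_trainer = NULL, folds = 10L, seed = 1L,
                        resample = FALSE) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  if (is.null(make_trainer))
    make_trainer <- function(row)
      rf_trainer(ntree = row$ntree, mtry = row$mtry, nodesize = row$nodesize)
  baccs <- vapply(seq_len(nrow(grid)), function(i) {
    cross_validate(X, y, folds = folds, trainer = make_trainer(grid[i, ]),
                   seed = seed, resample = resample)$bacc
  }, numeric(1))
  best <- which.max(baccs)     # ties -> first row in grid order
  list(best = grid[best, , drop = FALSE], best_bacc = baccs[best],
       scores = baccs)
}

#' Default random-forest hyperparameter grid
#'
#' Trees in \{100, 200, 500\}, mtry in \{sqrt, log2\}, minimum node size
#' in \{1, 3\}.
#'
#' @return data.frame with columns `ntree`, `mtry`, `nodesize`.
#' @export
rf_default_grid <- function() {
  expand.grid(ntree = c(100L, 200L, 500L), mtry = c("sqrt", "log2"),
              nodesize = c(1L, 3L), stringsAsFactors = FALSE)
}
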