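#' Per-feature relevance: |Pearson correlation| with the class label
#'
#' Constant features have undefined correlation and score 0 by convention.
#'
#' @param X feature matrix (samples x features).
#' @param y binary 0/1 label vector.
#' @return numeric vector of scores in \[0, 1\], named by feature.
#' @export
pearson_relevance <- function(X, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  r <- suppressWarnings(as.numeric(cor(X, y)))
  r[is.na(r)] <- 0               # constant feature convention
  out <- abs(r)
  names(out) <- colnames(X)
  out
}

.minmax_cols <- function(X) {
  apply(X, 2, function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  })
}

.feature_distance_matrix <- function(X, metric) {
  D <- ncol(X)
  if (metric == "euclidean")
    return(as.matrix(dist(t(X))))
  # cosine / tanimoto on feature columns
  G <- crossprod(X)                     # D x D gram matrix
  nrm2 <- diag(G)
  zero <- nrm2 == 0
  if (any(zero))
    warning("zero-vector feature column(s) under ", metric,
            " distance; distance set to 1")
  M <- if (metric == "cosine")
    1 - G / sqrt(outer(nrm2, nrm2))
  else
    1 - G / (outer(nrm2, nrm2, "+") - G)
  M[zero, ] <- 1
  M[, zero] <- 1
  diag(M) <- 0
  dimnames(M) <- list(colnames(X), colnames(X))
  M
}

.minmax_offdiag <- function(M) {
  off <- M[row(M) != col(M)]
  rng <- range(off)
  if (rng[1] == rng[2]) { M[] <- 0; return(M) }
  M2 <- (M - rng[1]) / diff(rng)
  diag(M2) <- 0
  M2
}

#' Per-feature redundancy distance
#'
#' For each feature, the mean distance between its (min-max scaled) column
#' and every other feature column. Larger values mean lower redundancy.
#' `mean3` (default) averages the Euclidean, cosine and Tanimoto distance
#' matrices after min-max normalizing each to \[0, 1\], so no single scale
#' dominates.
#'
#' @param X feature matrix (>= 2 features).
#' @param metric one of `"mean3"`, `"euclidean"`, `"cosine"`, `"tanimoto"`.
#' @return numeric vector of mean distances, named by feature.
#' @export
distance_redundancy <- function(X, metric = c("mean3", "euclidean",
                                              "cosine", "tanimoto")) {
  metric <- match.arg(metric)
  if (ncol(X) < 2L) stop("need >= 2 features")
  Xs <- .minmax_cols(X)
  M <- if (metric == "mean3") {
    ms <- lapply(c("euclidean", "cosine", "tanimoto"), function(m)
      .minmax_offdiag(.feature_distance_matrix(Xs, m)))
    (ms[[1]] + ms[[2]] + ms[[3]]) / 3
  } else {
    .feature_distance_matrix(Xs, metric)
  }
  out <- rowSums(M) / (ncol(X) - 1)
  names(out) <- colnames(X)
  out
}

#' MRMD feature ranking (max relevance, max distance)
#'
#' Ranks features by `relevance + redundancy_distance`, where relevance is
#' the absolute Pearson correlation with the class label and
#' redundancy_distance the mean distance to all other features (low
#' redundancy = high distance). Ties are broken by original column index.
#'
#' @inheritParams pearson_relevance
#' @param metric distance metric, see [distance_redundancy()].
#' @return an object of class `mrmd_ranking`: a data.frame with columns
#'   `rank`, `feature`, `index`, `relevance`, `redundancy`,
#'   `combined_score`, ordered best first.
#' @export
mrmd_rank <- function(X, y, metric = "mean3") {
  rel <- pearson_relevance(X, y)
  red <- distance_redundancy(X, metric)
  score <- rel + red
  ord <- order(-score, seq_along(score))
  out <- data.frame(rank = seq_along(ord),
                    feature = colnames(X)[ord],
                    index = ord,
                    relevance = unname(rel[ord]),
                    redundancy = unname(red[ord]),
                    combined_score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("mrmd_ranking", "data.frame")
  out
}

#' Write an MRMD ranking as TSV
#' @param ranking an `mrmd_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Incremental feature selection (IFS) over an MRMD ranking
#'
#' Evaluates nested top-k prefixes of the ranking by stratified
#' cross-validation (BACC is the selection metric) and picks the smallest
#' k achieving the maximum BACC. Resampling, when enabled, is applied
#' inside each training fold (see [cross_validate()]).
#'
#' @param ranking an `mrmd_ranking`.
#' @param X,y feature matrix and labels the ranking refers to.
#' @param folds number of CV folds.
#' @param trainer classifier spec from [rf_trainer()] and friends.
#' @param seed integer seed (same folds reused for every prefix size).
#' @param step evaluate k = step, 2*step, ... plus the full dimension
#'   (step = 1 evaluates every prefix).
#' @param resample apply SMOTE-Tomek within training folds.
#' @param verbose print progress.
#' @return object of class `ifs_result`: list with `curve` (data.frame of
#'   k, bacc, sn, sp, mcc, auc), `best_k`, `best_score`.
#' @export
ifs_search <- function(ranking, X, y, folds = 10L, trainer = rf_trainer(),
                       seed = 1L, step = 1L, resample = FALSE,
                       verbose = FALSE) {
  D <- nrow(ranking)
  ks <- unique(c(seq(step, D, by = step), D))
  rows <- lapply(ks, function(k) {
    sel <- ranking$index[seq_len(k)]
    rep <- cross_validate(X[, sel, drop = FALSE], y, folds = folds,
                          trainer = trainer, seed = seed,
                          resample = resample)
    if (verbose) message("IFS k=", k, " BACC=", round(rep$bacc, 4))
    data.frame(k = k, bacc = rep$bacc, sn = rep$sn, sp = rep$sp,
               mcc = rep$mcc, auc = rep$auc)
  })
  curve <- do.call(rbind, rows)
  best_row <- which(curve$bacc == max(curve$bacc))[1]  # ties -> smallest k
  structure(list(curve = curve,
                 best_k = curve$k[best_row],
                 best_score = curve$bacc[best_row]),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("IFS over", nrow(x$curve), "prefix sizes; best k =", x$best_k,
      "with CV BACC =", round(x$best_score, 4), "\n")
  invisible(x)
}
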