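#' Train the full TTCA classification pipeline
#'
#' End-to-end training on a labeled peptide dataset: encode under the
#' hybrid feature set, rank features by MRMD, pick the optimal prefix by
#' incremental feature selection (cross-validated BACC), and fit the
#' final random-forest model on the selected features of the full
#' training set (after SMOTE-Tomek rebalancing when `resample = TRUE`).
#'
#' @param ds labeled `peptide_dataset`.
#' @param schemes encoder schemes, see [encode_dataset()].
#' @param lambda,weight PAAC parameters.
#' @param folds CV folds for IFS.
#' @param ifs_step IFS prefix step size (1 = every prefix; larger steps
#'   trade resolution for speed).
#' @param resample rebalance with SMOTE-Tomek (inside CV training folds
#'   during IFS, and on the full training set for the final fit).
#' @param k_neighbors SMOTE neighborhood size.
#' @param trainer classifier spec (default [rf_trainer()]).
#' @param metric MRMD distance metric.
#' @param seed integer seed.
#' @param verbose print progress.
#' @return object of class `ttca_model`: list with the fitted classifier,
#'   `selected_features`, `ranking`, `ifs`, `cv_report` (CV at best_k),
#'   encoder configuration and `threshold`.
#' @export
train_pipeline <- function(ds, schemes = c("gpsd", "gaapc", "paac"),
                           lambda = 2L, weight = 0.05, folds = 10L,
                           ifs_step = 1L, resample = TRUE,
                           k_neighbors = 5L, trainer = rf_trainer(),
                           metric = "mean3", seed = 1L, verbose = FALSE) {
  if (anyNA(ds$label)) stop("all training records must be labeled")
  X <- encode_dataset(ds, schemes = schemes, lambda = lambda, weight = weight)
  y <- ds$label
  ranking <- mrmd_rank(X, y, metric = metric)
  ifs <- ifs_search(ranking, X, y, folds = folds, trainer = trainer,
                    seed = seed, step = ifs_step, resample = resample,
                    verbose = verbose)
  sel <- ranking$index[seq_len(ifs$best_k)]
  Xsel <- X[, sel, drop = FALSE]
  cv_report <- cross_validate(Xsel, y, folds = folds, trainer = trainer,
                              seed = seed, resample = resample,
                              k_neighbors = k_neighbors)
  Xfit <- Xsel; yfit <- y
  if (resample) {
    res <- smote_tomek(Xsel, y, k_neighbors = k_neighbors, seed = seed)
    Xfit <- res$X_out; yfit <- res$y_out
  }
  model <- trainer$fit(Xfit, yfit, seed = seed)
  structure(list(model = model, trainer_name = trainer$name,
                 trainer = trainer,
                 selected_features = colnames(X)[sel],
                 ranking = ranking, ifs = ifs, cv_report = cv_report,
                 encoder_config = list(schemes = schemes, lambda = lambda,
                                       weight = weight),
                 threshold = 0.5, resample = resample, seed = seed,
                 version = 1L),
            class = "ttca_model")
}

#' @export
print.ttca_model <- function(x, ...) {
  cat("ttca_model (", x$trainer_name, ")\n", sep = "")
  cat("  encoders:", paste(x$encoder_config$schemes, collapse = "+"),
      "->", length(x$selected_features), "selected features\n")
  cat("  CV at best_k: "); print(x$cv_report)
  invisible(x)
}

#' Predict TTCA labels and scores for new peptides
#'
#' Encodes the records with the bundle's encoder configuration, selects
#' the bundle's features (same names, same order), and thresholds the
#' positive-class probability. Records failing an encoder length
#' precondition get a per-record error entry; valid records are still
#' scored.
#'
#' @param object a `ttca_model`.
#' @param ds a `peptide_dataset` (labels not required).
#' @param ... unused.
#' @return data.frame in input order with columns `id`, `score`, `label`
#'   (NA where the record could not be encoded) and `error` (message or
#'   NA).
#' @export
predict.ttca_model <- function(object, ds, ...) {
  cfg <- object$encoder_config
  out <- data.frame(id = ds$id, score = NA_real_, label = NA_integer_,
                    error = NA_character_, stringsAsFactors = FALSE)
  encodable <- logical(nrow(ds))
  min_len <- max(c(1L, if ("gaapc" %in% cfg$schemes) 3L,
                   if ("asdc" %in% cfg$schemes) 2L,
                   if ("paac" %in% cfg$schemes) cfg$lambda + 1L))
  for (i in seq_len(nrow(ds))) {
    if (nchar(ds$sequence[i]) < min_len) {
      out$error[i] <- paste0("sequence shorter than required minimum ",
                             min_len)
    } else encodable[i] <- TRUE
  }
  if (any(encodable)) {
    sub <- ds[encodable, , drop = FALSE]
    X <- encode_dataset(sub, schemes = cfg$schemes, lambda = cfg$lambda,
                        weight = cfg$weight)
    miss <- setdiff(object$selected_features, colnames(X))
    if (length(miss))
      stop("encoding does not reproduce training features: ",
           paste(head(miss, 3), collapse = ", "))
    Xsel <- X[, object$selected_features, drop = FALSE]
    p <- object$trainer$predict_prob(object$model, Xsel)
    out$score[encodable] <- p
    out$label[encodable] <- as.integer(p >= object$threshold)
  }
  out
}

#' Evaluate a fitted model on a labeled dataset (independent test)
#'
#' @param model a `ttca_model`.
#' @param ds labeled `peptide_dataset`.
#' @return an `evaluation_report` (Sn, Sp, BACC, MCC, AUC).
#' @export
evaluate_model <- function(model, ds) {
  if (anyNA(ds$label)) stop("all records must be labeled for evaluation")
  pred <- predict(model, ds)
  if (anyNA(pred$score))
    stop("record(s) could not be encoded: ",
         paste(pred$id[is.na(pred$score)], collapse = ", "))
  rep <- compute_metrics(confusion_counts(ds$label, pred$label))
  structure(c(rep, list(auc = roc_auc(pred$score, ds$label),
                        scores = pred$score)),
            class = "evaluation_report")
}

#' Save / load a fitted model bundle
#'
#' The bundle (classifier state, selected feature names, encoder
#' configuration, version) is serialized with `saveRDS`.
#'
#' @param model a `ttca_model`.
#' @param path file path.
#' @return `path` invisibly; `load_model` returns the `ttca_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ttca_model")) stop("not a ttca_model bundle: ", path)
  m
}

#' Serialize an evaluation report as JSON-ready list / TSV
#'
#' @param report an `evaluation_report`.
#' @return named list of the five headline metrics.
#' @export
report_metrics <- function(report) {
  list(sn = report$sn, sp = report$sp, bacc = report$bacc,
       mcc = report$mcc, auc = report$auc)
}
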