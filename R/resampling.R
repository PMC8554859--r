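.euclid_dist_rows <- function(X) as.matrix(dist(X))

#' SMOTE minority over-sampling
#'
#' Generates synthetic minority samples by linear interpolation: pick a
#' minority sample x, one of its `k_neighbors` nearest minority-class
#' neighbors x' (Euclidean distance), a uniform u in \[0, 1\], and emit
#' x + u (x' - x). Sampling continues until the minority count reaches
#' `target_ratio` times the majority count.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y binary 0/1 labels; the minority class is the rarer one.
#' @param k_neighbors number of nearest minority neighbors to draw from;
#'   the minority class must contain more than `k_neighbors` samples.
#' @param target_ratio desired minority/majority ratio after sampling
#'   (default 1 = fully balanced).
#' @param seed integer seed; output is deterministic given the seed.
#' @return object of class `resample_result`: list with `X_out`, `y_out`,
#'   `n_synthetic`, `is_synthetic` (logical per output row),
#'   `removed_pairs` (NULL here; filled by [smote_tomek()]), `seed`.
#' @export
smote <- function(X, y, k_neighbors = 5L, target_ratio = 1, seed = 1L) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  tab <- table(factor(y, levels = c(0L, 1L)))
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  min_idx <- which(y == minority)
  n_min <- length(min_idx); n_maj <- length(y) - n_min
  if (n_min <= k_neighbors)
    stop("minority class has ", n_min, " samples; needs > k_neighbors (",
         k_neighbors, ") - use a smaller k")
  n_target <- ceiling(target_ratio * n_maj)
  n_syn <- max(0L, n_target - n_min)

  syn <- NULL
  if (n_syn > 0L) {
    set.seed(seed)
    Dm <- .euclid_dist_rows(X[min_idx, , drop = FALSE])
    diag(Dm) <- Inf
    nn <- apply(Dm, 1, function(d) order(d)[seq_len(k_neighbors)])
    nn <- if (k_neighbors == 1L) matrix(nn, ncol = 1L) else t(nn)
    base <- sample(seq_len(n_min), n_syn, replace = TRUE)
    nb <- nn[cbind(base, sample(seq_len(k_neighbors), n_syn, replace = TRUE))]
    u <- runif(n_syn)
    A <- X[min_idx[base], , drop = FALSE]
    B <- X[min_idx[nb], , drop = FALSE]
    syn <- A + u * (B - A)
    rownames(syn) <- paste0("synthetic_", seq_len(n_syn))
  }
  X_out <- rbind(X, syn)
  y_out <- c(y, rep(minority, n_syn))
  structure(list(X_out = X_out, y_out = y_out, n_synthetic = n_syn,
                 is_synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_syn)),
                 removed_pairs = NULL, seed = seed),
            class = "resample_result")
}

#' Tomek link detection
#'
#' A Tomek link is a pair of opposite-class samples that are mutual
#' nearest neighbors (Euclidean distance; ties broken by smaller index).
#'
#' @param X numeric feature matrix.
#' @param y binary 0/1 labels (both classes non-empty).
#' @return integer matrix with two columns (`i`, `j`), one row per link,
#'   i < j; zero rows when no links exist.
#' @export
tomek_links <- function(X, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  D <- .euclid_dist_rows(X)
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)       # ties: first (smallest) index
  n <- length(y)
  links <- which(nn[nn] == seq_len(n) &   # mutual nearest neighbors
                 y != y[nn] &
                 seq_len(n) < nn)         # report each pair once, i < j
  cbind(i = links, j = unname(nn[links]))
}

#' SMOTE-Tomek hybrid resampling
#'
#' SMOTE over-samples the minority class to a 1:1 ratio, then every
#' sample participating in a Tomek link of the post-SMOTE data is removed
#' (both members of each link), cleaning the class boundary.
#'
#' @inheritParams smote
#' @param remove what to delete per link: `"both"` members (classical
#'   SMOTE-Tomek cleaning, default) or `"majority"` member only.
#' @return a `resample_result` with `removed_pairs` holding the link index
#'   pairs (indices into the post-SMOTE matrix) and counts updated.
#' @export
smote_tomek <- function(X, y, k_neighbors = 5L, seed = 1L,
                        remove = c("both", "majority")) {
  remove <- match.arg(remove)
  res <- smote(X, y, k_neighbors = k_neighbors, target_ratio = 1, seed = seed)
  links <- tomek_links(res$X_out, res$y_out)
  drop_idx <- if (nrow(links) == 0L) integer(0)
  else if (remove == "both") unique(as.vector(links[, c("i", "j")]))
  else {
    tab <- table(factor(res$y_out, levels = c(0L, 1L)))
    maj <- if (tab[["1"]] > tab[["0"]]) 1L else 0L
    unique(as.vector(links)[res$y_out[as.vector(links)] == maj])
  }
  keep <- setdiff(seq_along(res$y_out), drop_idx)
  structure(list(X_out = res$X_out[keep, , drop = FALSE],
                 y_out = res$y_out[keep],
                 n_synthetic = res$n_synthetic,
                 is_synthetic = res$is_synthetic[keep],
                 removed_pairs = links, seed = seed),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat("resample_result:", length(x$y_out), "samples (",
      sum(x$y_out == 1), "pos /", sum(x$y_out == 0), "neg ),",
      x$n_synthetic, "synthetic,",
      if (is.null(x$removed_pairs)) 0 else nrow(x$removed_pairs),
      "Tomek links removed\n")
  invisible(x)
}
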