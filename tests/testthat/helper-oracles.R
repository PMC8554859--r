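# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and share no code with R/.

random_peptide <- function(min_len = 8, max_len = 30) {
  L <- sample(min_len:max_len, 1)
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

# ASDC by explicit double loop over all index pairs i < j
asdc_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  lev <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  counts <- setNames(numeric(400), lev)
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    key <- paste0(ch[i], ch[j])
    counts[key] <- counts[key] + 1
  }
  counts / (L * (L - 1) / 2)
}

# CTD for one property partition by direct enumeration
ctd_oracle_one <- function(seq, partition) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  grp <- vapply(ch, function(a) {
    for (g in names(partition)) if (a %in% partition[[g]]) return(g)
    stop("unassigned residue")
  }, character(1))
  C <- vapply(c("g1", "g2", "g3"), function(g) sum(grp == g) / L, numeric(1))
  Tc <- c(g1g2 = 0, g1g3 = 0, g2g3 = 0)
  if (L >= 2) for (i in 1:(L - 1)) {
    a <- grp[i]; b <- grp[i + 1]
    if (a != b) {
      key <- paste0(sort(c(a, b)), collapse = "")
      Tc[key] <- Tc[key] + 1
    }
  }
  Tc <- Tc / (L - 1)
  D <- numeric(0)
  for (g in c("g1", "g2", "g3")) {
    pos <- which(grp == g)
    n <- length(pos)
    vals <- if (n == 0) rep(0, 5) else {
      picks <- c(1, max(1, ceiling(0.25 * n)), max(1, ceiling(0.5 * n)),
                 max(1, ceiling(0.75 * n)), n)
      pos[picks] / L
    }
    D <- c(D, vals)
  }
  c(C, Tc, D)
}

# Pearson correlation from the closed form, looped
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(0)
  abs(num / den)
}

# MRMD scores recomputed from scratch with explicit pairwise loops
mrmd_oracle <- function(X, y, metric = "mean3") {
  D <- ncol(X)
  rel <- vapply(seq_len(D), function(f) pearson_oracle(X[, f], y), numeric(1))
  Xs <- apply(X, 2, function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  })
  dmat <- function(kind) {
    M <- matrix(0, D, D)
    for (i in 1:D) for (j in 1:D) {
      if (i == j) next
      a <- Xs[, i]; b <- Xs[, j]
      M[i, j] <- switch(kind,
        euclidean = sqrt(sum((a - b)^2)),
        cosine = if (sum(a^2) == 0 || sum(b^2) == 0) 1 else
          1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
        tanimoto = if (sum(a^2) == 0 || sum(b^2) == 0) 1 else
          1 - sum(a * b) / (sum(a^2) + sum(b^2) - sum(a * b)))
    }
    M
  }
  norm01 <- function(M) {
    off <- M[row(M) != col(M)]
    if (max(off) == min(off)) { M[] <- 0; return(M) }
    M2 <- (M - min(off)) / (max(off) - min(off)); diag(M2) <- 0; M2
  }
  M <- if (metric == "mean3") {
    (norm01(dmat("euclidean")) + norm01(dmat("cosine")) +
       norm01(dmat("tanimoto"))) / 3
  } else dmat(metric)
  red <- vapply(seq_len(D), function(f) sum(M[f, -f]) / (D - 1), numeric(1))
  score <- rel + red
  list(relevance = rel, redundancy = red, score = score,
       order = order(-score, seq_len(D)))
}

# AUC by counting concordant positive/negative pairs (ties = 1/2)
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Tomek links by explicit mutual-nearest-neighbor scan
tomek_oracle <- function(X, y) {
  n <- nrow(X)
  D <- as.matrix(dist(X)); diag(D) <- Inf
  nn <- integer(n)
  for (i in 1:n) nn[i] <- which.min(D[i, ])
  out <- NULL
  for (i in 1:n) {
    j <- nn[i]
    if (j > i && nn[j] == i && y[i] != y[j]) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}
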