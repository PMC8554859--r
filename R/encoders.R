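.seq_chars <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) == 0L) stop("empty sequence")
  if (any(!ch %in% AA_ALPHABET))
    stop("sequence contains non-standard residue '",
         ch[!ch %in% AA_ALPHABET][1], "'")
  ch
}

#' Amino acid composition (AAC)
#'
#' Per-residue frequency over the 20 standard amino acids; components sum
#' to 1.
#'
#' @param seq a peptide sequence (single string).
#' @return named numeric 20-vector (names = residue letters).
#' @export
encode_aac <- function(seq) {
  ch <- .seq_chars(seq)
  counts <- table(factor(ch, levels = AA_ALPHABET))
  v <- as.numeric(counts) / length(ch)
  names(v) <- AA_ALPHABET
  v
}

#' Composition/transition/distribution (CTD) descriptor
#'
#' For each of eight physicochemical properties the residues are mapped to
#' one of three groups, then three blocks are computed: C, the frequency
#' of each group (3 values); T, the frequency of adjacent-position
#' transitions between *distinct* groups, counted as unordered group pairs
#' and divided by L-1 (3 values); D, for each group the sequence positions
#' (as a fraction of L, in (0, 1]) at which the first, 25%, 50%, 75% and
#' last residue of that group occur (15 values). A group absent from the
#' sequence contributes five zeros to D. 8 x (3 + 3 + 15) = 168 features.
#'
#' @param seq a peptide sequence.
#' @param table property partition table from [ctd_property_table()].
#' @return named numeric 168-vector (`<property>.C.g1`,
#'   `<property>.T.g1g2`, `<property>.D.g1.first` ... `.last`).
#' @export
encode_ctd <- function(seq, table = ctd_property_table()) {
  ch <- .seq_chars(seq)
  L <- length(ch)
  if (L < 2L) warning("sequence length < 2: transition block is all zero")
  out <- numeric(0)
  for (p in names(table)) {
    grp_of <- character(0)
    for (g in names(table[[p]])) grp_of[table[[p]][[g]]] <- g
    g <- grp_of[ch]

    comp <- as.numeric(table(factor(g, levels = c("g1", "g2", "g3")))) / L
    names(comp) <- paste0(p, ".C.", c("g1", "g2", "g3"))

    tr <- c(g1g2 = 0, g1g3 = 0, g2g3 = 0)
    if (L >= 2L) {
      a <- g[-L]; b <- g[-1]
      key <- ifelse(a < b, paste0(a, b), paste0(b, a))
      key <- key[a != b]
      if (length(key)) {
        tk <- table(factor(key, levels = c("g1g2", "g1g3", "g2g3")))
        tr <- as.numeric(tk) / (L - 1)
        names(tr) <- c("g1g2", "g1g3", "g2g3")
      }
    }
    names(tr) <- paste0(p, ".T.", c("g1g2", "g1g3", "g2g3"))

    dist <- numeric(0)
    for (grp in c("g1", "g2", "g3")) {
      pos <- which(g == grp)
      n <- length(pos)
      vals <- if (n == 0L) rep(0, 5) else
        pos[c(1L, pmax(1L, ceiling(c(0.25, 0.5, 0.75) * n)), n)] / L
      names(vals) <- paste0(p, ".D.", grp, ".",
                            c("first", "p25", "p50", "p75", "last"))
      dist <- c(dist, vals)
    }
    out <- c(out, comp, tr, dist)
  }
  out
}

#' Global protein sequence descriptor (GPSD, 188 features)
#'
#' Concatenation of the amino acid composition (20) and the CTD descriptor
#' over eight physicochemical properties (168).
#'
#' @inheritParams encode_ctd
#' @return named numeric 188-vector with `GPSD.`-prefixed names.
#' @export
encode_gpsd <- function(seq, table = ctd_property_table()) {
  aac <- encode_aac(seq)
  names(aac) <- paste0("GPSD.AAC.", names(aac))
  ctd <- encode_ctd(seq, table)
  names(ctd) <- paste0("GPSD.CTD.", names(ctd))
  c(aac, ctd)
}

.groups_of <- function(ch) .group5_of[ch]

#' Grouped amino acid composition (GAAC, 5 features)
#'
#' Frequency of each of the five physicochemical residue groups,
#' N(c) / L; components sum to 1.
#'
#' @param seq a peptide sequence.
#' @param groups group definition, defaults to [AA_GROUPS5].
#' @return named numeric 5-vector (`c1`..`c5`).
#' @export
encode_gaac <- function(seq, groups = AA_GROUPS5) {
  ch <- .seq_chars(seq)
  g <- .groups_of(ch)
  v <- as.numeric(table(factor(g, levels = names(groups)))) / length(ch)
  names(v) <- names(groups)
  v
}

#' Grouped dipeptide composition (GDPC, 25 features)
#'
#' Frequency of each ordered pair of residue groups over adjacent
#' positions, N_xy / (L - 1).
#'
#' @inheritParams encode_gaac
#' @return named numeric 25-vector (`c1.c1`, `c1.c2`, ...).
#' @export
encode_gdpc <- function(seq, groups = AA_GROUPS5) {
  ch <- .seq_chars(seq)
  L <- length(ch)
  if (L < 2L) stop("GDPC requires sequence length >= 2")
  g <- .groups_of(ch)
  key <- paste0(g[-L], ".", g[-1])
  lev <- as.vector(t(outer(names(groups), names(groups), paste, sep = ".")))
  v <- as.numeric(table(factor(key, levels = lev))) / (L - 1)
  names(v) <- lev
  v
}

#' Grouped tripeptide composition (GTPC, 125 features)
#'
#' Frequency of each ordered triple of residue groups over adjacent
#' positions, N_xyz / (L - 2).
#'
#' @inheritParams encode_gaac
#' @return named numeric 125-vector (`c1.c1.c1`, ...).
#' @export
encode_gtpc <- function(seq, groups = AA_GROUPS5) {
  ch <- .seq_chars(seq)
  L <- length(ch)
  if (L < 3L) stop("GTPC requires sequence length >= 3")
  g <- .groups_of(ch)
  key <- paste0(g[1:(L - 2)], ".", g[2:(L - 1)], ".", g[3:L])
  gn <- names(groups)
  lev <- as.vector(vapply(gn, function(x)
    as.vector(vapply(gn, function(y) paste(x, y, gn, sep = "."),
                     character(length(gn)))), character(length(gn)^2)))
  v <- as.numeric(table(factor(key, levels = lev))) / (L - 2)
  names(v) <- lev
  v
}

#' Grouped amino acid and peptide composition (GAAPC, 155 features)
#'
#' Concatenation of GAAC (5), GDPC (25) and GTPC (125).
#'
#' @inheritParams encode_gaac
#' @return named numeric 155-vector with `GAAPC.`-prefixed names.
#' @export
encode_gaapc <- function(seq, groups = AA_GROUPS5) {
  a <- encode_gaac(seq, groups); names(a) <- paste0("GAAPC.GAAC.", names(a))
  d <- encode_gdpc(seq, groups); names(d) <- paste0("GAAPC.GDPC.", names(d))
  t <- encode_gtpc(seq, groups); names(t) <- paste0("GAAPC.GTPC.", names(t))
  c(a, d, t)
}

#' Adaptive skip dipeptide composition (ASDC, 400 features)
#'
#' For every ordered residue pair (a, b), the number of index pairs
#' i < j with seq[i] = a and seq[j] = b — i.e. dipeptides with any number
#' of intervening residues — divided by the total number of index pairs
#' L(L-1)/2. Components sum to 1.
#'
#' @param seq a peptide sequence (length >= 2).
#' @return named numeric 400-vector (`ASDC.AA`, `ASDC.AC`, ...).
#' @export
encode_asdc <- function(seq) {
  ch <- .seq_chars(seq)
  L <- length(ch)
  if (L < 2L) stop("ASDC requires sequence length >= 2")
  lev <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  # counts over all skip distances: for each gap k, adjacent-at-distance-k pairs
  counts <- integer(length(lev)); names(counts) <- lev
  for (k in 1:(L - 1)) {
    key <- paste0(ch[1:(L - k)], ch[(1 + k):L])
    tk <- table(key)
    counts[names(tk)] <- counts[names(tk)] + as.integer(tk)
  }
  v <- counts / (L * (L - 1) / 2)
  names(v) <- paste0("ASDC.", lev)
  v
}

#' Type-1 pseudo amino acid composition (PAAC, 20 + lambda features)
#'
#' Residue frequencies augmented with lambda sequence-order correlation
#' factors. The j-th factor is the mean over positions i of
#' Theta(R_i, R_(i+j)), where Theta(a, b) is the mean squared difference
#' of three standardized properties (hydrophobicity, hydrophilicity,
#' side-chain mass). Frequencies f and factors theta are jointly
#' normalized: component u = f_u / (sum f + w sum theta) for u <= 20 and
#' w theta_j / (same) beyond, so all components sum to 1. The defaults
#' lambda = 2, w = 0.05 give a 22-dimensional vector.
#'
#' @param seq a peptide sequence of length > `lambda`.
#' @param lambda number of correlation factors (rank of sequence-order
#'   effects); must be < sequence length.
#' @param weight weighting factor w for the correlation part.
#' @param props standardized property matrix from [paac_property_values()].
#' @return named numeric (20 + lambda)-vector (`PAAC.f.A`...,
#'   `PAAC.theta.1`...).
#' @export
encode_paac <- function(seq, lambda = 2L, weight = 0.05,
                        props = paac_property_values()) {
  ch <- .seq_chars(seq)
  L <- length(ch)
  lambda <- as.integer(lambda)
  if (lambda < 1L) stop("lambda must be >= 1")
  if (weight <= 0) stop("weight must be > 0")
  if (L <= lambda)
    stop("PAAC with lambda = ", lambda, " requires sequence length >= ",
         lambda + 1L, " (got ", L, ")")
  H <- props[ch, , drop = FALSE]
  theta <- vapply(seq_len(lambda), function(j) {
    d <- H[1:(L - j), , drop = FALSE] - H[(1 + j):L, , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
  f <- as.numeric(table(factor(ch, levels = AA_ALPHABET))) / L
  denom <- sum(f) + weight * sum(theta)
  v <- c(f / denom, weight * theta / denom)
  names(v) <- c(paste0("PAAC.f.", AA_ALPHABET),
                paste0("PAAC.theta.", seq_len(lambda)))
  v
}

#' Encode a peptide dataset under one or more schemes
#'
#' Applies the selected encoders to every record and returns the
#' column-wise concatenation. Records failing an encoder's minimum-length
#' precondition are reported together in a single error (no silent drops).
#'
#' @param ds a `peptide_dataset`.
#' @param schemes character vector from `"gpsd"`, `"gaapc"`, `"asdc"`,
#'   `"paac"`, `"aac"`, `"gaac"`; default is the hybrid GPSD + GAAPC +
#'   PAAC set (365 features).
#' @param lambda,weight PAAC parameters.
#' @param ctd_table,paac_props,groups underlying tables (overridable).
#' @return numeric matrix, rows = records (rownames = ids), columns =
#'   uniquely named features.
#' @export
encode_dataset <- function(ds, schemes = c("gpsd", "gaapc", "paac"),
                           lambda = 2L, weight = 0.05,
                           ctd_table = ctd_property_table(),
                           paac_props = paac_property_values(),
                           groups = AA_GROUPS5) {
  schemes <- match.arg(schemes, c("gpsd", "gaapc", "asdc", "paac",
                                  "aac", "gaac"), several.ok = TRUE)
  min_len <- c(gpsd = 1L, gaapc = 3L, asdc = 2L, paac = lambda + 1L,
               aac = 1L, gaac = 1L)
  need <- max(min_len[schemes])
  too_short <- nchar(ds$sequence) < need
  if (any(too_short))
    stop("record(s) shorter than the required minimum length ", need,
         " for scheme(s) ", paste(schemes, collapse = "+"), ": ",
         paste(ds$id[too_short], collapse = ", "))
  enc1 <- function(s) {
    parts <- lapply(schemes, function(sc) switch(
      sc,
      gpsd  = encode_gpsd(s, ctd_table),
      gaapc = encode_gaapc(s, groups),
      asdc  = encode_asdc(s),
      paac  = encode_paac(s, lambda, weight, paac_props),
      aac   = { v <- encode_aac(s); names(v) <- paste0("AAC.", names(v)); v },
      gaac  = { v <- encode_gaac(s, groups)
                names(v) <- paste0("GAAC.", names(v)); v }))
    unlist(parts)
  }
  rows <- lapply(ds$sequence, enc1)
  X <- do.call(rbind, rows)
  rownames(X) <- ds$id
  if (anyDuplicated(colnames(X))) stop("duplicate feature names")
  X
}

#' Column-wise concatenation of feature matrices
#'
#' All parts must cover the same samples in the same order; feature names
#' must stay unique after concatenation.
#'
#' @param parts list of feature matrices with identical rownames.
#' @return combined feature matrix.
#' @export
concat_features <- function(parts) {
  if (!length(parts)) stop("no feature matrices supplied")
  ids <- rownames(parts[[1]])
  for (p in parts)
    if (!identical(rownames(p), ids))
      stop("sample ids differ between feature matrices")
  X <- do.call(cbind, parts)
  if (anyDuplicated(colnames(X)))
    stop("duplicate feature names after concatenation")
  X
}
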