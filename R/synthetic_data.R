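#' Generate a labeled synthetic peptide dataset
#'
#' Negative sequences draw residues i.i.d. from a background distribution
#' (uniform over the 20 residues by default). Positive sequences draw
#' from the background tilted toward the aromatic (c2) and positively
#' charged (c3) groups: residues in c2 and c3 get their background weight
#' multiplied by `exp(signal_strength)` before renormalization, so
#' `signal_strength = 0` makes the two classes identically distributed
#' and larger values give a stronger compositional class signal (one the
#' grouped-composition features capture directly). Lengths are uniform on
#' `length_range`.
#'
#' @param n_pos,n_neg class sizes.
#' @param length_range integer min/max peptide length (min >= 3 so every
#'   encoder applies).
#' @param signal_strength log-fold tilt of c2/c3 residue frequencies in
#'   positives (>= 0).
#' @param seed integer seed; output is deterministic given the seed.
#' @param background optional length-20 residue probability vector (named
#'   by residue); default uniform.
#' @return labeled `peptide_dataset` (positives first).
#' @export
generate_peptides <- function(n_pos = 300L, n_neg = 300L,
                              length_range = c(8L, 25L),
                              signal_strength = 1, seed = 1L,
                              background = NULL) {
  if (length_range[1] < 3L) stop("minimum length must be >= 3")
  if (length_range[2] < length_range[1]) stop("invalid length range")
  if (signal_strength < 0) stop("signal_strength must be >= 0")
  if (is.null(background)) {
    background <- rep(1 / 20, 20)
    names(background) <- AA_ALPHABET
  }
  background <- background[AA_ALPHABET] / sum(background)
  tilt <- background
  boost <- names(tilt) %in% c(AA_GROUPS5$c2, AA_GROUPS5$c3)
  tilt[boost] <- tilt[boost] * exp(signal_strength)
  tilt <- tilt / sum(tilt)

  set.seed(seed)
  draw <- function(n, p, prefix) {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    data.frame(id = sprintf("%s_%04d", prefix, seq_len(n)), sequence = seqs,
               stringsAsFactors = FALSE)
  }
  pos <- draw(n_pos, tilt, "pos")
  neg <- draw(n_neg, background, "neg")
  peptide_dataset(c(pos$id, neg$id), c(pos$sequence, neg$sequence),
                  c(rep(1L, n_pos), rep(0L, n_neg)))
}

#' Generate an imbalanced synthetic peptide dataset
#'
#' Positives are the majority class (as in typical TTCA benchmark sets);
#' the minority fraction `ratio` fixes the negative count at
#' `round(n * ratio)`.
#'
#' @param n total number of peptides.
#' @param ratio minority (negative) fraction in (0, 0.5).
#' @param ... passed to [generate_peptides()] (`length_range`,
#'   `signal_strength`, `seed`, `background`).
#' @return labeled `peptide_dataset`.
#' @export
generate_imbalanced <- function(n = 985L, ratio = 393 / 985, ...) {
  if (ratio <= 0 || ratio >= 0.5) stop("ratio must be in (0, 0.5)")
  n_neg <- round(n * ratio)
  generate_peptides(n_pos = n - n_neg, n_neg = n_neg, ...)
}
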