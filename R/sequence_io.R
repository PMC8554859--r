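#' Construct a validated peptide dataset
#'
#' The central data container: an ordered set of peptide records, each an
#' id, an uppercase sequence over the 20 standard amino-acid letters, and
#' an optional binary label (1 = TTCA, 0 = non-TTCA).
#'
#' @param ids character vector of unique non-empty record ids.
#' @param sequences character vector of peptide sequences.
#' @param labels optional integer vector of 0/1 labels (NA allowed when a
#'   record is unlabeled).
#' @param residue_policy what to do with sequences containing letters
#'   outside the 20-letter alphabet: `"reject"` (default) raises an error
#'   naming the record and the offending character; `"drop"` removes the
#'   record with a warning.
#' @param dedup_sequences drop records whose sequence duplicates an
#'   earlier record's (first occurrence kept), mirroring benchmark-set
#'   construction where duplicate peptides are eliminated.
#' @return an object of class `peptide_dataset`: a data.frame with columns
#'   `id`, `sequence`, `label`.
#' @export
peptide_dataset <- function(ids, sequences, labels = NULL,
                            residue_policy = c("reject", "drop"),
                            dedup_sequences = FALSE) {
  residue_policy <- match.arg(residue_policy)
  ids <- as.character(ids)
  sequences <- as.character(sequences)
  if (length(ids) != length(sequences))
    stop("ids and sequences must have the same length")
  if (any(!nzchar(ids)) || anyNA(ids)) stop("record ids must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1])

  lowered <- sequences != toupper(sequences)
  if (any(lowered)) {
    warning(sum(lowered), " sequence(s) contained lowercase letters; uppercased")
    sequences <- toupper(sequences)
  }
  if (any(!nzchar(sequences)))
    stop("empty sequence for record: ", ids[!nzchar(sequences)][1])

  bad_char <- vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- ch[!ch %in% AA_ALPHABET]
    if (length(bad)) bad[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (any(!is.na(bad_char))) {
    offenders <- which(!is.na(bad_char))
    if (residue_policy == "reject") {
      stop("record '", ids[offenders[1]], "' contains non-standard residue '",
           bad_char[offenders[1]], "'")
    }
    warning("dropping ", length(offenders),
            " record(s) with non-standard residues: ",
            paste(head(ids[offenders], 5), collapse = ", "))
    keep <- setdiff(seq_along(ids), offenders)
    ids <- ids[keep]; sequences <- sequences[keep]
    if (!is.null(labels)) labels <- labels[keep]
  }

  if (is.null(labels)) {
    labels <- rep(NA_integer_, length(ids))
  } else {
    labels <- as.integer(labels)
    if (length(labels) != length(ids))
      stop("labels must match the number of records")
    if (any(!labels %in% c(0L, 1L) & !is.na(labels)))
      stop("labels must be 0, 1 or NA")
  }

  if (dedup_sequences && anyDuplicated(sequences)) {
    dup <- duplicated(sequences)
    warning("removed ", sum(dup), " duplicate sequence(s)")
    ids <- ids[!dup]; sequences <- sequences[!dup]; labels <- labels[!dup]
  }

  structure(
    data.frame(id = ids, sequence = sequences, label = labels,
               stringsAsFactors = FALSE),
    class = c("peptide_dataset", "data.frame")
  )
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat("peptide_dataset:", nrow(x), "records\n")
  cat("  lengths:", if (nrow(x)) paste0(min(nchar(x$sequence)), "-",
                                        max(nchar(x$sequence))) else "-", "\n")
  cc <- class_counts(x)
  cat("  labels: ", cc[["1"]], " positive / ", cc[["0"]], " negative / ",
      cc[["unlabeled"]], " unlabeled\n", sep = "")
  invisible(x)
}

#' Per-class record counts of a dataset
#'
#' @param ds a `peptide_dataset`.
#' @return named integer vector with elements `"1"`, `"0"`, `"unlabeled"`.
#' @export
class_counts <- function(ds) {
  c("1" = sum(ds$label == 1L, na.rm = TRUE),
    "0" = sum(ds$label == 0L, na.rm = TRUE),
    "unlabeled" = sum(is.na(ds$label)))
}

#' Read peptides from a FASTA file
#'
#' Parses with `Biostrings::readAAStringSet` and validates every record.
#' Labels may come from a two-column TSV (`id<TAB>label`, no header
#' required if the columns are named `id` and `label`; a headerless file
#' is accepted) and/or from a `|1` / `|0` suffix on the FASTA header; the
#' TSV wins on conflict.
#'
#' @param path FASTA file path.
#' @param labels optional path to a label TSV, or a named vector/data.frame
#'   of labels keyed by id.
#' @param residue_policy,dedup_sequences passed to [peptide_dataset()].
#' @return a `peptide_dataset` in file order.
#' @export
read_fasta <- function(path, labels = NULL,
                       residue_policy = c("reject", "drop"),
                       dedup_sequences = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(peptide_dataset(character(0), character(0)))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)          # token before first whitespace
  seqs <- as.character(set)

  # header-suffix label convention: ">id|1" / ">id|0"
  hdr_lab <- rep(NA_integer_, length(ids))
  has_suffix <- grepl("\\|[01]$", ids)
  hdr_lab[has_suffix] <- as.integer(sub("^.*\\|", "", ids[has_suffix]))
  ids[has_suffix] <- sub("\\|[01]$", "", ids[has_suffix])

  lab <- hdr_lab
  if (!is.null(labels)) {
    tab <- read_label_table(labels)
    hit <- match(ids, names(tab))
    lab[!is.na(hit)] <- unname(tab[hit[!is.na(hit)]])
  }
  peptide_dataset(ids, seqs, lab, residue_policy = residue_policy,
                  dedup_sequences = dedup_sequences)
}

#' Read a two-column id/label table
#'
#' @param labels a file path (TSV, optional `id`/`label` header), a
#'   data.frame with columns `id` and `label`, or an already-named vector.
#' @return named integer vector of 0/1 labels keyed by id.
#' @export
read_label_table <- function(labels) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    first <- readLines(labels, n = 1L)
    has_header <- grepl("^id\\tlabel$", first)
    tab <- read.delim(labels, header = has_header,
                      col.names = c("id", "label"),
                      stringsAsFactors = FALSE)
  } else if (is.data.frame(labels)) {
    tab <- labels[, c("id", "label")]
  } else if (!is.null(names(labels))) {
    tab <- data.frame(id = names(labels), label = as.integer(labels),
                      stringsAsFactors = FALSE)
  } else {
    stop("labels must be a TSV path, a data.frame or a named vector")
  }
  out <- as.integer(tab$label)
  if (any(!out %in% c(0L, 1L))) stop("labels must be 0 or 1")
  names(out) <- as.character(tab$id)
  if (anyDuplicated(names(out))) stop("duplicate id in label table")
  out
}

#' Write a peptide dataset to FASTA (and optionally a label TSV)
#'
#' Labels are written as `|1` / `|0` header suffixes so a FASTA round trip
#' preserves them; `label_path` additionally writes the TSV convention.
#'
#' @param ds a `peptide_dataset`.
#' @param path output FASTA path.
#' @param label_path optional output TSV path for labels.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path, label_path = NULL) {
  hdr <- ifelse(is.na(ds$label), ds$id, paste0(ds$id, "|", ds$label))
  set <- Biostrings::AAStringSet(ds$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 70L)
  if (!is.null(label_path)) {
    keep <- !is.na(ds$label)
    write.table(data.frame(id = ds$id[keep], label = ds$label[keep]),
                label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a dataset summary TSV (id, length, label)
#'
#' @param ds a `peptide_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_summary <- function(ds, path) {
  write.table(data.frame(id = ds$id, length = nchar(ds$sequence),
                         label = ds$label),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Randomly assigns a fixed fraction of each class to the test partition,
#' taking `floor(class size * test_fraction)` test samples per class (the
#' remainder stays in training). With 592 positives and 393 negatives at
#' 20% this yields the conventional 470/122 and 318/75 partition.
#'
#' @param ds labeled `peptide_dataset` (no NA labels).
#' @param test_fraction proportion in (0, 1) assigned to the test set.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with elements `train` and `test`, both `peptide_dataset`s.
#' @export
split_train_test <- function(ds, test_fraction = 0.2, seed = 1L) {
  if (anyNA(ds$label)) stop("all records must be labeled for splitting")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(ds$label == cl)
    n_test <- floor(length(idx) * test_fraction)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(ds)), test_idx)
  list(train = ds[train_idx, , drop = FALSE],
       test = ds[test_idx, , drop = FALSE])
}

#' @export
`[.peptide_dataset` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id", "sequence", "label") %in% names(out)))
    class(out) <- c("peptide_dataset", "data.frame")
  out
}
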