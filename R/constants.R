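#' @importFrom stats cor dist glm predict quantile runif sd
#' @importFrom utils head read.delim write.table
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical order; every sequence handled by the package is validated
#' against this alphabet.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Five physicochemical amino-acid groups
#'
#' The grouped-composition encoders (GAAC, GDPC, GTPC) collapse the 20
#' residues into five categories: `c1` aliphatic (GAVLMI), `c2` aromatic
#' (FYW), `c3` positively charged (KRH), `c4` negatively charged (DE),
#' `c5` uncharged/polar (STCPNQ).
#'
#' @export
AA_GROUPS5 <- list(
  c1 = c("G", "A", "V", "L", "M", "I"),
  c2 = c("F", "Y", "W"),
  c3 = c("K", "R", "H"),
  c4 = c("D", "E"),
  c5 = c("S", "T", "C", "P", "N", "Q")
)

# residue -> group id lookup ("c1".."c5"), built once at load time
.group5_of <- local({
  m <- character(0)
  for (g in names(AA_GROUPS5)) m[AA_GROUPS5[[g]]] <- g
  m
})

.read_versioned_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load the CTD physicochemical property partition table
#'
#' Eight properties, each splitting the 20 residues into three disjoint
#' groups; shipped as a versioned TSV in `inst/extdata`. Returns a named
#' list (one element per property) of named lists `g1`/`g2`/`g3`, each a
#' character vector of residues.
#'
#' @param path optional path to an alternative partition table with the
#'   same columns (`property`, `group`, `residues`).
#' @return named list of per-property partitions.
#' @export
ctd_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ctd_property_groups.tsv",
                        package = "pepTTCA", mustWork = TRUE)
  }
  tab <- .read_versioned_tsv(path)
  props <- unique(tab$property)
  out <- lapply(props, function(p) {
    rows <- tab[tab$property == p, ]
    grp <- lapply(rows$residues, function(s) strsplit(s, "")[[1]])
    names(grp) <- rows$group
    grp
  })
  names(out) <- props
  for (p in props) {
    all_res <- sort(unname(unlist(out[[p]])))
    if (!identical(all_res, sort(AA_ALPHABET)))
      stop("property '", p, "' does not partition the 20-letter alphabet")
  }
  out
}

#' Load the PAAC per-residue property values
#'
#' Hydrophobicity, hydrophilicity and side-chain mass for the 20 residues,
#' standardized (mean 0, population SD 1 across residues) as required by
#' the pseudo amino acid composition correlation function.
#'
#' @param path optional path to an alternative table (columns `residue`
#'   plus one column per property).
#' @param standardize standardize each property across the 20 residues
#'   (default TRUE; the raw table is returned otherwise).
#' @return numeric matrix, 20 rows (residues) x properties.
#' @export
paac_property_values <- function(path = NULL, standardize = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "paac_properties.tsv",
                        package = "pepTTCA", mustWork = TRUE)
  }
  tab <- .read_versioned_tsv(path)
  m <- as.matrix(tab[, setdiff(colnames(tab), "residue"), drop = FALSE])
  rownames(m) <- tab$residue
  m <- m[AA_ALPHABET, , drop = FALSE]
  if (standardize) {
    m <- apply(m, 2, function(v) {
      mu <- mean(v)
      s <- sqrt(mean((v - mu)^2))   # population SD, PseAAC convention
      (v - mu) / s
    })
    rownames(m) <- AA_ALPHABET
  }
  m
}
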