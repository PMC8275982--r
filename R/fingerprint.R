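#' Column fingerprint
#'
#' Identifies an alignment column by which residue occurrence of each taxon it
#' places together: for every taxon that is not gapped in the column, the
#' fingerprint records the 0-based ordinal of that residue within the taxon's
#' ungapped sequence. Two columns from different alignments of the same
#' sequences are "identically aligned" exactly when their fingerprints are
#' equal; the encoding is invariant to where the column sits in its alignment
#' and to gap placement elsewhere.
#'
#' @param x an \code{msa} object.
#' @param col column index (1-based).
#' @return named integer vector over all taxa (sorted by id), giving the
#'   residue ordinal, with \code{NA} marking a gap.
#' @examples
#' a <- msa(c(s1 = "AC-A", s2 = "A-CA"))
#' column_fingerprint(a, 3)  # s1 gapped, s2 places its 2nd residue (ordinal 1)
#' @export
column_fingerprint <- function(x, col) {
  stopifnot(inherits(x, "msa"))
  col <- as.integer(col)
  if (length(col) != 1 || is.na(col) || col < 1 || col > x$length)
    stop("column index out of range [1, ", x$length, "]")
  ids <- sort(x$ids)
  m <- x$chars[ids, , drop = FALSE]
  nongap <- m != "-"
  ord <- t(apply(nongap, 1, cumsum)) - nongap  # 0-based ordinal where non-gap
  out <- ifelse(nongap[, col], ord[, col], NA_integer_)
  stats::setNames(as.integer(out), ids)
}

# all column fingerprints of an msa as key strings, plus eligibility.
# Key: "taxonIndex:ordinal" joined by "|", taxa in sorted-id order, gapped taxa
# omitted. Columns with < 2 non-gap entries are ineligible: they carry no
# pairwise alignment information and never count as matches.
column_fingerprints <- function(x) {
  ids <- sort(x$ids)
  m <- x$chars[ids, , drop = FALSE]
  nongap <- m != "-"
  ord <- t(apply(nongap, 1, cumsum)) - nongap
  keys <- vapply(seq_len(ncol(m)), function(j) {
    tx <- which(nongap[, j])
    paste(tx, ord[tx, j], sep = ":", collapse = "|")
  }, character(1))
  list(keys = keys, eligible = colSums(nongap) >= 2)
}
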