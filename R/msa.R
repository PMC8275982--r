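#' Multiple sequence alignment object
#'
#' Constructs a gap-padded multiple sequence alignment from named character
#' strings (one per taxon) or from a character matrix with one row per taxon.
#' Residues are upper-cased and the alternative gap symbol \code{"."} is
#' normalised to \code{"-"} so that output from different aligners is
#' comparable.
#'
#' Validation enforces: unique taxon ids, equal row lengths, at least one
#' column, at least one non-gap residue per row, and no all-gap column.
#'
#' @param rows named character vector of aligned (gapped) sequences, or a
#'   character matrix with taxon ids as row names and one character per cell.
#' @param label free-text source name, typically the aligner that produced the
#'   alignment.
#' @param validate set to \code{FALSE} to skip invariant checks (used
#'   internally for bootstrap replicates, which may transiently violate the
#'   no-all-gap-row rule).
#' @return an object of class \code{"msa"}: a list with elements \code{ids},
#'   \code{chars} (character matrix), \code{length} (column count) and
#'   \code{label}.
#' @examples
#' a <- msa(c(s1 = "AC-A", s2 = "A-CA", s3 = "ACCA"))
#' a$length
#' @export
msa <- function(rows, label = "msa", validate = TRUE) {
  if (is.matrix(rows)) {
    m <- rows
    if (is.null(rownames(m))) stop("alignment matrix must have taxon ids as row names")
  } else {
    if (is.null(names(rows)) || any(!nzchar(names(rows))))
      stop("alignment rows must be named by taxon id")
    if (length(unique(nchar(rows))) > 1) {
      lens <- nchar(rows)
      bad <- names(rows)[lens != lens[1]][1]
      stop("ragged alignment: row '", bad, "' has length ", nchar(rows[bad]),
           ", expected ", lens[1])
    }
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    rownames(m) <- names(rows)
  }
  m <- toupper(m)
  m[m == "."] <- "-"
  obj <- structure(
    list(ids = rownames(m), chars = m, length = ncol(m), label = label),
    class = "msa")
  if (validate) validate_msa(obj)
  obj
}

validate_msa <- function(x) {
  if (anyDuplicated(x$ids))
    stop("duplicate taxon id: '", x$ids[duplicated(x$ids)][1], "'")
  if (x$length < 1) stop("alignment has no columns")
  gap <- x$chars == "-"
  all_gap_row <- rowSums(!gap) == 0
  if (any(all_gap_row))
    stop("row '", x$ids[all_gap_row][1], "' contains no residues")
  all_gap_col <- colSums(!gap) == 0
  if (any(all_gap_col))
    stop("all-gap column at position ", which(all_gap_col)[1])
  invisible(x)
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment '", x$label, "': ",
      length(x$ids), " taxa, ", x$length, " columns\n", sep = "")
  n <- min(length(x$ids), 8L)
  w <- min(x$length, 60L)
  for (i in seq_len(n)) {
    cat(format(x$ids[i], width = 12), " ",
        paste(x$chars[i, seq_len(w)], collapse = ""),
        if (x$length > w) "..." else "", "\n", sep = "")
  }
  if (length(x$ids) > n) cat("  ... and", length(x$ids) - n, "more taxa\n")
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) x$chars

#' Aligned rows as gapped strings
#'
#' @param x an \code{msa} object.
#' @return named character vector, one gapped string per taxon.
#' @export
msa_strings <- function(x) {
  stopifnot(inherits(x, "msa"))
  stats::setNames(apply(x$chars, 1, paste, collapse = ""), x$ids)
}

#' Ungapped sequences of an alignment
#'
#' @param x an \code{msa} object.
#' @return named character vector of residue strings with all gaps removed.
#' @export
ungapped <- function(x) {
  stopifnot(inherits(x, "msa"))
  out <- apply(x$chars, 1, function(r) paste(r[r != "-"], collapse = ""))
  stats::setNames(out, x$ids)
}

#' Column subset of an alignment
#'
#' Extracts columns by index, with repetition allowed — the primitive behind
#' bootstrap replicate materialisation.
#'
#' @param x an \code{msa} object.
#' @param idx integer vector of column indices (1-based; duplicates allowed).
#' @param label label of the resulting alignment.
#' @return an \code{msa} with \code{length(idx)} columns, row order preserved.
#' @export
subset_columns <- function(x, idx, label = x$label) {
  stopifnot(inherits(x, "msa"))
  idx <- as.integer(idx)
  if (length(idx) < 1) stop("at least one column index is required")
  if (any(idx < 1L | idx > x$length))
    stop("column index out of range [1, ", x$length, "]")
  msa(x$chars[, idx, drop = FALSE], label = label, validate = FALSE)
}

#' Test whether alignments align the same underlying sequences
#'
#' Alternative alignments of one sequence set differ only in gap placement:
#' they must share the same taxon ids and, per taxon, identical ungapped
#' residue strings.
#'
#' @param msas non-empty list of \code{msa} objects.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' a <- msa(c(s1 = "AC-A", s2 = "A-CA"))
#' b <- msa(c(s1 = "ACA-", s2 = "-ACA"))
#' check_same_sequences(list(a, b))
#' @export
check_same_sequences <- function(msas) {
  if (length(msas) < 1) stop("empty alignment list")
  stopifnot(all(vapply(msas, inherits, logical(1), "msa")))
  ref <- ungapped(msas[[1]])
  ref <- ref[order(names(ref))]
  for (m in msas[-1]) {
    u <- ungapped(m)
    u <- u[order(names(u))]
    if (!identical(names(u), names(ref)) || !identical(unname(u), unname(ref)))
      return(FALSE)
  }
  TRUE
}

# reorder rows of an msa to a given id order (error on mismatch)
harmonize_rows <- function(x, ids) {
  if (!setequal(x$ids, ids)) {
    miss <- setdiff(ids, x$ids)
    extra <- setdiff(x$ids, ids)
    stop("taxon set mismatch in '", x$label, "'",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  msa(x$chars[ids, , drop = FALSE], label = x$label, validate = FALSE)
}
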