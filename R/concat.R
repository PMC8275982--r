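#' Concatenate alternative alignments into a Super-MSA
#'
#' Column-wise concatenation of two or more alternative alignments of the same
#' sequences, in the style of a supermatrix. Rows are harmonised by taxon id
#' to the order of the first alignment; each column keeps a provenance record
#' of the alignment it came from, and per-source sampling weights are
#' initialised with \code{\link{compute_sample_weights}}.
#'
#' @param msas list of two or more \code{msa} objects of the same sequences.
#' @return object of class \code{"super_msa"}: list with \code{alignment}
#'   (the concatenated \code{msa}), \code{provenance} (integer source index
#'   per column), \code{source_lengths}, \code{source_labels} and
#'   \code{weights} (a \code{sample_weights} object; normalised weights sum
#'   to 100).
#' @examples
#' a <- msa(c(s1 = "AC-A", s2 = "A-CA"), label = "alnA")
#' b <- msa(c(s1 = "ACA-", s2 = "-ACA"), label = "alnB")
#' sm <- super_msa(list(a, b))
#' sm$alignment$length  # 8
#' @export
super_msa <- function(msas) {
  if (length(msas) < 2)
    stop("a Super-MSA needs at least two alternative alignments; ",
         "for a single alignment use the standard bootstrap")
  if (!check_same_sequences(msas))
    stop("alignments do not share the same sequence set: ",
         paste(unique(unlist(lapply(msas, function(m) m$ids))), collapse = ", "))
  labs <- msa_labels(msas)
  for (i in seq_along(msas)) msas[[i]]$label <- labs[i]
  ids <- msas[[1]]$ids
  msas <- lapply(msas, harmonize_rows, ids = ids)
  lens <- vapply(msas, function(m) m$length, integer(1))
  chars <- do.call(cbind, lapply(msas, function(m) m$chars))
  structure(
    list(alignment = msa(chars, label = "super", validate = TRUE),
         provenance = rep(seq_along(msas), lens),
         source_lengths = stats::setNames(lens, labs),
         source_labels = labs,
         weights = compute_sample_weights(msas)),
    class = "super_msa")
}

#' @export
print.super_msa <- function(x, ...) {
  cat("Super-MSA:", length(x$source_labels), "source alignments,",
      length(x$alignment$ids), "taxa,", x$alignment$length, "columns\n")
  print(round(data.frame(length = x$source_lengths,
                         weight = x$weights$normalized), 3))
  invisible(x)
}

#' Write the per-column provenance of a Super-MSA
#'
#' Emits a TSV sidecar with columns \code{column_index} (1-based),
#' \code{source_index} (1-based) and \code{source_label}.
#'
#' @param x a \code{super_msa}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_provenance <- function(x, path) {
  stopifnot(inherits(x, "super_msa"))
  df <- data.frame(column_index = seq_along(x$provenance),
                   source_index = x$provenance,
                   source_label = x$source_labels[x$provenance])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
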