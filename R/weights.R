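#' Column similarity between two alternative alignments
#'
#' The percentage of columns of \code{x} that are found identically aligned
#' within \code{y}: a column of \code{x} matches when its residue-ordinal
#' fingerprint (see \code{\link{column_fingerprint}}) occurs among the
#' fingerprints of \code{y}'s columns. Columns with fewer than two non-gap
#' residues are excluded from both numerator and denominator — a single
#' residue cannot be "aligned" with anything. The measure is directional
#' (x-side denominator) and not required to be symmetric.
#'
#' @param x,y \code{msa} objects aligning the same sequences.
#' @return a percentage in \code{[0, 100]}, at full floating precision.
#' @export
column_sim <- function(x, y) {
  if (!check_same_sequences(list(x, y)))
    stop("'", x$label, "' and '", y$label, "' do not align the same sequences")
  fx <- column_fingerprints(x)
  fy <- column_fingerprints(y)
  if (!any(fx$eligible))
    stop("'", x$label, "' has no column with >= 2 residues")
  100 * mean(fx$keys[fx$eligible] %in% fy$keys[fy$eligible])
}

#' Pairwise column-similarity matrix
#'
#' @param msas list of two or more \code{msa} objects of the same sequences.
#' @return square numeric matrix of \code{column_sim} percentages; entry
#'   \code{[x, y]} is the percentage of \code{x}'s columns matched in
#'   \code{y}. Diagonal is 100.
#' @export
similarity_matrix <- function(msas) {
  n <- length(msas)
  if (n < 2) stop("at least two alignments are required")
  if (!check_same_sequences(msas))
    stop("alignments do not share the same sequence set")
  labs <- msa_labels(msas)
  fps <- lapply(msas, column_fingerprints)
  S <- matrix(100, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    ei <- fps[[i]]$eligible
    if (!any(ei)) stop("'", labs[i], "' has no column with >= 2 residues")
    for (j in seq_len(n)) {
      if (i == j) next
      S[i, j] <- 100 * mean(fps[[i]]$keys[ei] %in%
                            fps[[j]]$keys[fps[[j]]$eligible])
    }
  }
  S
}

#' Per-alignment bootstrap sampling weights
#'
#' Each alignment's raw weight is 100 minus its mean column similarity to the
#' other alternatives, so an aligner producing output unlike anyone else's is
#' up-weighted and a crowd-follower down-weighted. Raw weights are normalised
#' to sum to 100. When all alignments are mutually identical every raw weight
#' is 0 and the normalised weights fall back to uniform (100/N each), which
#' reduces weighted sampling to the standard bootstrap.
#'
#' @param msas list of two or more \code{msa} objects of the same sequences.
#' @param sim optional precomputed \code{\link{similarity_matrix}}.
#' @return object of class \code{"sample_weights"}: list with \code{labels},
#'   \code{raw}, \code{normalized} (sums to 100) and \code{similarity}.
#' @examples
#' a <- msa(c(s1 = "AAA--", s2 = "-CCC-", s3 = "--GGG"), label = "A")
#' b <- msa(a$chars, label = "B")
#' c <- msa(c(s1 = "--AAA", s2 = "CCC--", s3 = "-GGG-"), label = "C")
#' compute_sample_weights(list(a, b, c))$normalized  # 25, 25, 50
#' @export
compute_sample_weights <- function(msas, sim = NULL) {
  if (length(msas) < 2) stop("at least two alignments are required")
  if (is.null(sim)) sim <- similarity_matrix(msas)
  n <- nrow(sim)
  raw <- vapply(seq_len(n), function(i) 100 - mean(sim[i, -i]), numeric(1))
  tot <- sum(raw)
  normalized <- if (tot < 1e-9) rep(100 / n, n) else 100 * raw / tot
  structure(list(labels = rownames(sim), raw = stats::setNames(raw, rownames(sim)),
                 normalized = stats::setNames(normalized, rownames(sim)),
                 similarity = sim),
            class = "sample_weights")
}

#' @export
print.sample_weights <- function(x, ...) {
  cat("Sampling weights over", length(x$labels), "alternative alignments\n")
  print(round(data.frame(raw = x$raw, normalized = x$normalized), 3))
  invisible(x)
}

msa_labels <- function(msas) {
  labs <- vapply(msas, function(m) m$label, character(1))
  if (anyDuplicated(labs)) labs <- make.unique(labs, sep = "_")
  labs
}
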