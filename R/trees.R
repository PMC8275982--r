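#' Parse and serialise newick trees
#'
#' Thin wrappers over \pkg{ape} that enforce the package's conventions: trees
#' are unrooted objects (a rooted input has its root suppressed), degree-2
#' nodes are collapsed, and duplicate leaf labels are an error. Supports, when
#' present, travel as internal-node labels — the de facto newick standard.
#'
#' @param text a newick string.
#' @return \code{parse_newick}: an \pkg{ape} \code{phylo} object.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' bipartitions(tr)
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick string: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: '", tr$tip.label[duplicated(tr$tip.label)][1], "'")
  if (any(!nzchar(tr$tip.label))) stop("empty leaf label")
  tr <- ape::collapse.singles(tr)
  if (ape::Ntip(tr) > 2 && ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr
}

#' @rdname parse_newick
#' @param tree a \code{phylo} object.
#' @return \code{write_newick}: a newick string (with trailing semicolon).
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

# canonical key of a split: the smaller side's sorted labels joined by ",";
# ties on size broken lexicographically. NULL for trivial splits.
canonical_split <- function(side, all_labels) {
  other <- setdiff(all_labels, side)
  if (length(side) < 2 || length(other) < 2) return(NULL)
  a <- paste(sort(side), collapse = ",")
  b <- paste(sort(other), collapse = ",")
  if (length(side) < length(other)) a
  else if (length(other) < length(side)) b
  else min(a, b)
}

# non-trivial canonical split keys of an unrooted tree (character vector)
split_keys <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 4) return(character(0))
  tree <- ape::unroot(ape::collapse.singles(tree))
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    k <- canonical_split(labs[idx], labs)
    if (is.null(k)) NA_character_ else k
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Non-trivial bipartitions of a tree
#'
#' Every internal edge of an unrooted tree splits the taxa in two; the split
#' is non-trivial when both sides hold at least two taxa. Bipartitions are
#' returned in canonical form: the smaller side (ties broken
#' lexicographically), sorted.
#'
#' @param tree a \code{phylo} object (rooted input is unrooted first).
#' @return named list of character vectors, one per non-trivial bipartition;
#'   names are the canonical key (sorted labels joined by commas). A fully
#'   resolved n-leaf unrooted tree yields exactly n - 3; trees with fewer than
#'   4 leaves yield none.
#' @export
bipartitions <- function(tree) {
  keys <- split_keys(tree)
  stats::setNames(lapply(keys, function(k) strsplit(k, ",", fixed = TRUE)[[1]]),
                  keys)
}

check_leaf_sets <- function(reference, replicates) {
  ref_labs <- reference$tip.label
  for (i in seq_along(replicates)) {
    labs <- replicates[[i]]$tip.label
    if (!setequal(labs, ref_labs)) {
      miss <- setdiff(ref_labs, labs)
      stop("replicate ", i, " does not share the reference leaf set",
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Whole-topology bootstrap support
#'
#' The fraction of replicate trees topologically identical to the reference:
#' identical bipartition sets, i.e. unrooted Robinson-Foulds distance zero. A
#' polytomous replicate never matches a fully resolved reference.
#'
#' @param reference a \code{phylo} reference tree.
#' @param replicates non-empty list of \code{phylo} trees on the same leaves.
#' @return a fraction in \code{[0, 1]}.
#' @export
topology_support <- function(reference, replicates) {
  if (length(replicates) < 1) stop("empty replicate list")
  check_leaf_sets(reference, replicates)
  ref_keys <- split_keys(reference)
  hits <- vapply(replicates, function(tr) {
    k <- split_keys(tr)
    length(k) == length(ref_keys) && setequal(k, ref_keys)
  }, logical(1))
  mean(hits)
}

#' Per-clade bootstrap supports
#'
#' For every non-trivial bipartition of the reference tree, the fraction of
#' replicate trees whose bipartition set contains it.
#'
#' @inheritParams topology_support
#' @return object of class \code{"support_report"}: list with
#'   \code{tree_support} (whole-topology fraction), \code{clade_supports}
#'   (named fraction vector keyed by canonical bipartition),
#'   \code{bipartitions} (the corresponding taxon sets) and
#'   \code{replicate_count}.
#' @export
clade_supports <- function(reference, replicates) {
  if (length(replicates) < 1) stop("empty replicate list")
  check_leaf_sets(reference, replicates)
  ref_keys <- split_keys(reference)
  rep_keys <- lapply(replicates, split_keys)
  m <- length(replicates)
  counts <- vapply(ref_keys, function(k)
    sum(vapply(rep_keys, function(rk) k %in% rk, logical(1))), numeric(1))
  n_match <- sum(vapply(rep_keys, function(rk)
    length(rk) == length(ref_keys) && setequal(rk, ref_keys), logical(1)))
  structure(list(
    tree_support = n_match / m,
    clade_supports = stats::setNames(counts / m, ref_keys),
    bipartitions = stats::setNames(
      lapply(ref_keys, function(k) strsplit(k, ",", fixed = TRUE)[[1]]), ref_keys),
    replicate_count = m), class = "support_report")
}

#' @export
print.support_report <- function(x, ...) {
  cat("Bootstrap support over", x$replicate_count, "replicates\n")
  cat("  whole-topology support:",
      sprintf("%.1f%%", 100 * x$tree_support), "\n")
  if (length(x$clade_supports)) {
    cat("  clade supports:\n")
    for (k in names(x$clade_supports))
      cat(sprintf("    %5.1f%%  {%s}\n", 100 * x$clade_supports[[k]], k))
  }
  invisible(x)
}

#' Frequencies of all splits observed in a tree set
#'
#' Tabulates every non-trivial bipartition occurring in any of the trees and
#' returns its frequency (fraction of trees containing it) — the support a
#' majority-rule consensus would use, and the basis for comparing supports of
#' clades inside and outside a known true tree.
#'
#' @param trees non-empty list of \code{phylo} trees on a common leaf set.
#' @return named numeric vector of fractions, keyed by canonical split.
#' @export
split_frequencies <- function(trees) {
  if (length(trees) < 1) stop("empty tree list")
  keys <- unlist(lapply(trees, split_keys))
  if (length(keys) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(keys)
  stats::setNames(as.numeric(tab) / length(trees), names(tab))
}

#' Neighbor-joining tree from an alignment
#'
#' Builds a p-distance matrix (mismatches over jointly non-gap sites, pairwise
#' deletion, no multiple-hit correction) and runs neighbor joining via
#' \code{ape::nj}. Deterministic: repeated calls on the same alignment return
#' the same tree. Intended as the self-contained inference engine for
#' simulation studies and bootstrap replicates; for publication-grade trees
#' plug in an external maximum-likelihood program via
#' \code{\link{infer_external}}.
#'
#' @param aln an \code{msa} with at least 4 sequences.
#' @return an unrooted \code{phylo} tree.
#' @export
nj_tree <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  n <- length(aln$ids)
  if (n < 4) stop("neighbor joining needs at least 4 sequences, got ", n)
  ape::unroot(ape::nj(p_distance(aln)))
}

#' Pairwise p-distance matrix
#'
#' @param aln an \code{msa}.
#' @return a symmetric numeric matrix of mismatch proportions over jointly
#'   non-gap sites (pairwise deletion).
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- aln$chars
  gap <- m == "-"
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cmp <- !(gap[i, ] | gap[j, ])
      nc <- sum(cmp)
      if (nc == 0)
        stop("no jointly non-gap site between '", aln$ids[i], "' and '",
             aln$ids[j], "'")
      d[i, j] <- d[j, i] <- sum(m[i, cmp] != m[j, cmp]) / nc
    }
  }
  d
}

#' Infer a tree with an external command
#'
#' Writes the alignment to a temporary FASTA file, substitutes the
#' \code{{input}} and \code{{output}} placeholders in the command template,
#' runs it through the shell, and parses the newick tree it writes. The exact
#' command line is attached to the result as attribute \code{"command"}.
#'
#' @param aln an \code{msa}.
#' @param command_template shell command containing \code{{input}} and
#'   \code{{output}} placeholders.
#' @return a \code{phylo} tree (unrooted).
#' @export
infer_external <- function(aln, command_template) {
  stopifnot(inherits(aln, "msa"))
  if (!grepl("{input}", command_template, fixed = TRUE) ||
      !grepl("{output}", command_template, fixed = TRUE))
    stop("command template must contain {input} and {output} placeholders")
  inp <- tempfile(fileext = ".fasta")
  out <- tempfile(fileext = ".nwk")
  on.exit(unlink(c(inp, out)))
  write_alignment(aln, inp, "fasta")
  cmd <- gsub("{output}", out,
              gsub("{input}", inp, command_template, fixed = TRUE), fixed = TRUE)
  res <- suppressWarnings(system2("sh", c("-c", shQuote(cmd)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("external command failed (exit ", status, "): ", cmd, "\n",
         paste(utils::tail(res, 10), collapse = "\n"))
  if (!file.exists(out) || file.size(out) == 0)
    stop("external command produced no output tree: ", cmd)
  tr <- parse_newick(paste(readLines(out, warn = FALSE), collapse = ""))
  attr(tr, "command") <- cmd
  tr
}

#' Standard (single-alignment) bootstrap supports
#'
#' The classic Felsenstein bootstrap on one alignment: replicates of the full
#' alignment length, columns drawn uniformly with replacement, a tree inferred
#' from each, supports measured against the reference. Serves as the baseline
#' the Super-MSA schemes are compared to.
#'
#' @param aln an \code{msa}.
#' @param reference reference \code{phylo}; defaults to \code{tree_fun(aln)}.
#' @param tree_fun function mapping an \code{msa} to a \code{phylo}.
#' @param count number of replicates.
#' @param seed integer master seed; \code{NULL} leaves the RNG state alone.
#' @return a \code{\link{clade_supports}} report, with the reference tree
#'   attached as attribute \code{"reference"}.
#' @export
bootstrap_supports <- function(aln, reference = NULL, tree_fun = nj_tree,
                               count = 100, seed = NULL) {
  stopifnot(inherits(aln, "msa"))
  if (is.null(reference)) reference <- tree_fun(aln)
  if (!is.null(seed)) set.seed(as.integer(seed))
  trees <- lapply(seq_len(count), function(i)
    tree_fun(subset_columns(aln, sample.int(aln$length, aln$length,
                                            replace = TRUE))))
  rep <- clade_supports(reference, trees)
  attr(rep, "reference") <- reference
  rep
}
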