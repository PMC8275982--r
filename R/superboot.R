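#' Super-MSA bootstrap support
#'
#' The package's central fitting function. Takes two or more alternative
#' alignments of the same sequences, concatenates them into a Super-MSA with
#' per-source sampling weights (divergent aligners up-weighted), draws
#' bootstrap replicates under the chosen scheme, infers a tree from each
#' replicate, and measures whole-topology and per-clade bootstrap supports
#' against a reference tree (by default inferred from the Super-MSA itself).
#'
#' Schemes: \code{"sboot"} resamples the full concatenated length uniformly;
#' \code{"psboot"} draws average-source-length replicates, N times as many;
#' \code{"wpsboot"} (default) additionally draws each column with probability
#' proportional to its source alignment's weight, discounting redundant
#' aligners.
#'
#' @param msas list of two or more \code{msa} objects of the same sequences
#'   (see \code{\link{read_alignment}}), or a \code{super_msa}.
#' @param scheme sampling scheme, see Details.
#' @param base_count baseline replicate number (default 100).
#' @param tree_fun tree inference function mapping an \code{msa} to a
#'   \code{phylo}; default \code{\link{nj_tree}}. Use a wrapper around
#'   \code{\link{infer_external}} for ML programs.
#' @param reference reference \code{phylo}; default: \code{tree_fun} applied
#'   to the Super-MSA.
#' @param seed integer master seed for the replicate draw.
#' @param keep_trees keep the replicate trees in the returned object.
#' @return object of class \code{"superboot"}: list with \code{super},
#'   \code{plan}, \code{scheme}, \code{weights}, \code{reference} (node
#'   labels carry percent supports), \code{tree_support},
#'   \code{clade_supports}, \code{report} (the \code{support_report}),
#'   \code{replicate_count}, \code{seed} and (optionally)
#'   \code{replicate_trees}.
#' @examples
#' tr <- parse_newick("((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2,(E:0.2,F:0.2):0.2);")
#' sim <- evolve_sequences(tr, root_length = 60, indel_rate = 0.05, seed = 1)
#' alts <- perturb_alignment(sim$alignment, n_variants = 3,
#'                           gap_shift_rate = 0.3, seed = 2)
#' fit <- superboot(alts, scheme = "wpsboot", base_count = 20, seed = 3)
#' fit
#' coef(fit)
#' @seealso \code{\link{bootstrap_supports}} for the single-alignment
#'   baseline; \code{\link{reduce_tree}} and \code{\link{rf_decompose}} for
#'   downstream evaluation.
#' @export
superboot <- function(msas, scheme = c("wpsboot", "psboot", "sboot"),
                      base_count = 100, tree_fun = nj_tree, reference = NULL,
                      seed = NULL, keep_trees = FALSE) {
  scheme <- match.arg(scheme)
  sm <- if (inherits(msas, "super_msa")) msas else super_msa(msas)
  plan <- make_plan(sm, scheme, base_count)
  reps <- draw_replicates(sm, plan, seed)
  if (is.null(reference)) reference <- tree_fun(sm$alignment)
  rep_trees <- lapply(reps, function(r) tree_fun(materialize(sm, r)))
  report <- clade_supports(reference, rep_trees)
  reference <- annotate_supports(reference, report$clade_supports)
  out <- list(call = match.call(), scheme = scheme, super = sm, plan = plan,
              weights = sm$weights, reference = reference,
              tree_support = report$tree_support,
              clade_supports = report$clade_supports, report = report,
              replicate_count = plan$replicate_count, seed = seed)
  if (keep_trees) out$replicate_trees <- rep_trees
  structure(out, class = "superboot")
}

# write percent supports into node labels of an unrooted tree
annotate_supports <- function(tree, supports) {
  tree <- ape::unroot(ape::collapse.singles(tree))
  n <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  tree$node.label <- vapply(seq_len(tree$Nnode), function(i) {
    k <- canonical_split(labs[pp[[i]]], labs)
    if (is.null(k) || !k %in% names(supports)) ""
    else sprintf("%g", round(100 * supports[[k]], 2))
  }, character(1))
  tree
}

#' @export
print.superboot <- function(x, ...) {
  cat("Super-MSA bootstrap (", x$scheme, ")\n", sep = "")
  cat("  sources: ", length(x$super$source_labels), " alignments, ",
      length(x$super$alignment$ids), " taxa, Super-MSA length ",
      x$super$alignment$length, "\n", sep = "")
  cat("  replicates: ", x$replicate_count, " of length ",
      x$plan$replicate_length, "\n", sep = "")
  cat("  sampling weights: ",
      paste(sprintf("%s=%.1f", x$weights$labels, x$weights$normalized),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  whole-topology support: %.1f%%\n", 100 * x$tree_support))
  if (length(x$clade_supports)) {
    cat("  clade supports:\n")
    for (k in names(x$clade_supports))
      cat(sprintf("    %5.1f%%  {%s}\n", 100 * x$clade_supports[[k]], k))
  }
  invisible(x)
}

#' @export
summary.superboot <- function(object, ...) {
  structure(list(fit = object,
                 similarity = object$weights$similarity,
                 newick = write_newick(object$reference)),
            class = "summary.superboot")
}

#' @export
print.summary.superboot <- function(x, ...) {
  print(x$fit)
  cat("  column-similarity matrix (%):\n")
  print(round(x$similarity, 2))
  cat("  annotated reference tree:\n  ", x$newick, "\n", sep = "")
  invisible(x)
}

#' @export
coef.superboot <- function(object, ...) object$clade_supports

#' @export
plot.superboot <- function(x, ...) {
  tr <- x$reference
  tr$edge.length <- NULL
  ape::plot.phylo(tr, type = "unrooted", lab4ut = "axial", ...)
  ape::nodelabels(tr$node.label, frame = "none", adj = c(1.1, -0.4),
                  cex = 0.8, col = "steelblue")
  invisible(x)
}
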