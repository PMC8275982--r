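#' All-or-nothing topology loss
#'
#' Loss 0 when the two unrooted topologies are identical (equal bipartition
#' sets; branch lengths ignored), loss 1 otherwise.
#'
#' @param estimate,truth \code{phylo} trees on the same leaf set.
#' @return 0 or 1 (integer).
#' @export
all_or_nothing <- function(estimate, truth) {
  check_leaf_sets(truth, list(estimate))
  a <- split_keys(estimate); b <- split_keys(truth)
  as.integer(!(length(a) == length(b) && setequal(a, b)))
}

#' Robinson-Foulds decomposition into Type I and Type II errors
#'
#' Compares the non-trivial bipartition sets of an estimated and a true tree:
#' \code{e1} (Type I, false positives) counts estimate clades absent from the
#' truth, \code{e2} (Type II, false negatives) counts true clades missing from
#' the estimate, and \code{rf = e1 + e2} is the Robinson-Foulds distance.
#'
#' @param estimate,truth \code{phylo} trees on the same leaf set (>= 4
#'   leaves).
#' @return object of class \code{"rf_decomposition"}: list with integer
#'   \code{e1}, \code{e2}, \code{rf}.
#' @examples
#' t1 <- parse_newick("((A,B),(C,(D,E)));")
#' t2 <- parse_newick("((A,C),(B,(D,E)));")
#' rf_decompose(t1, t2)  # one NNI apart: e1 = e2 = 1
#' @export
rf_decompose <- function(estimate, truth) {
  check_leaf_sets(truth, list(estimate))
  if (ape::Ntip(truth) < 4) stop("at least 4 leaves are required")
  a <- split_keys(estimate); b <- split_keys(truth)
  e1 <- length(setdiff(a, b))
  e2 <- length(setdiff(b, a))
  structure(list(e1 = e1, e2 = e2, rf = e1 + e2), class = "rf_decomposition")
}

#' @export
print.rf_decomposition <- function(x, ...) {
  cat("RF decomposition: e1 (Type I / FP) =", x$e1,
      ", e2 (Type II / FN) =", x$e2, ", RF =", x$rf, "\n")
  invisible(x)
}

#' Reduced bootstrap tree
#'
#' Collapses every internal edge whose bootstrap support is strictly below the
#' threshold \code{S} (in percent), creating polytomies; an edge with support
#' exactly \code{S} survives. Raising \code{S} trades Type I error (fewer
#' clades asserted, fewer can be wrong) against Type II error (more true
#' clades omitted). Branch lengths are not preserved — the reduced tree is a
#' topological object; surviving internal nodes carry their support (percent)
#' as node labels.
#'
#' @param tree reference \code{phylo} tree.
#' @param supports a \code{support_report} for \code{tree}, or a named vector
#'   of support fractions in \code{[0, 1]} keyed by canonical bipartition;
#'   every internal edge of \code{tree} must be covered.
#' @param S threshold in percent, in \code{[0, 100]}.
#' @return object of class \code{"reduced_tree"}: list with \code{tree} (a
#'   \code{phylo}, possibly multifurcating) and \code{threshold}.
#' @export
reduce_tree <- function(tree, supports, S) {
  if (inherits(supports, "support_report")) supports <- supports$clade_supports
  if (!is.numeric(S) || length(S) != 1 || S < 0 || S > 100)
    stop("S must be a percentage in [0, 100]")
  tree <- ape::unroot(ape::collapse.singles(tree))
  n <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  node_key <- vapply(pp, function(idx) {
    k <- canonical_split(labs[idx], labs)
    if (is.null(k)) NA_character_ else k
  }, character(1))
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$node.label <- rep("", tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next
    key <- node_key[child - n]
    if (is.na(key)) next  # trivial split (possible only on degenerate trees)
    if (!key %in% names(supports))
      stop("no support value for internal edge {", key, "}")
    sup <- supports[[key]]
    tree$node.label[child - n] <- sprintf("%g", round(100 * sup, 6))
    if (100 * sup < S) tree$edge.length[e] <- 0
  }
  reduced <- ape::di2multi(tree, tol = 0.5)
  reduced$edge.length <- NULL
  structure(list(tree = reduced, threshold = S), class = "reduced_tree")
}

#' @export
print.reduced_tree <- function(x, ...) {
  cat("Reduced bootstrap tree at threshold S =", x$threshold, "%:",
      length(split_keys(x$tree)), "surviving internal edges\n")
  cat(" ", write_newick(x$tree), "\n")
  invisible(x)
}

#' True-positive ranking curve
#'
#' Sorts items by descending score and records the cumulative (FP, TP) counts
#' reached after each distinct score value. Tied scores are consumed as a
#' block: a tie group is admitted in full or not at all, so the curve does not
#' depend on the input order of tied items.
#'
#' @param scores numeric vector of confidence scores (higher = more trusted).
#' @param labels logical (or 0/1) vector: \code{TRUE} for positives.
#' @return object of class \code{"ranking_curve"}: data frame with columns
#'   \code{score} (block threshold), \code{fp}, \code{tp}; the final row is
#'   \code{(total negatives, total positives)}.
#' @export
ranking_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  if (!any(labels) || all(labels)) stop("need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  blocks <- unique(s)
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- vapply(blocks, function(b) max(which(s == b)), integer(1))
  structure(data.frame(score = blocks, fp = fp[last], tp = tp[last]),
            class = c("ranking_curve", "data.frame"))
}

#' True positives within a false-positive budget
#'
#' @param curve a \code{\link{ranking_curve}}.
#' @param fp_budget maximum number of false positives accepted.
#' @return the largest TP count reachable with FP \code{<= fp_budget} under
#'   the whole-tie-block rule (0 when even the first block overshoots).
#' @export
tp_at_fp <- function(curve, fp_budget) {
  stopifnot(inherits(curve, "ranking_curve"))
  ok <- curve$fp <= fp_budget
  if (!any(ok)) 0L else max(curve$tp[ok])
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic
#' P(score_pos > score_neg) + 0.5 P(tie), which handles tied scores exactly
#' (mid-rank convention).
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) labels; \code{TRUE} for positives.
#' @return a value in \code{[0, 1]}.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Support-comparison contingency table
#'
#' Cross-tabulates datasets by the sign of \code{support_a - support_b}
#' (strata \code{">"}, \code{"="}, \code{"<"}) against whether the dataset's
#' tree matches the reference topology, and derives the percentage of correct
#' topologies within the \code{">"} and \code{"<"} strata. Typical use:
#' \code{support_a} is the wpSBOOT bootstrap and \code{support_b} the average
#' single-aligner bootstrap.
#'
#' @param support_a,support_b numeric supports in \code{[0, 100]}.
#' @param matches_reference logical: does the dataset's tree match the
#'   reference topology?
#' @param cutoff optional support cutoff; with \code{side = "above"} only
#'   datasets with both supports > cutoff are tabulated, with \code{"below"}
#'   only those with both supports <= cutoff.
#' @param side see \code{cutoff}.
#' @return object of class \code{"support_comparison"}: list with
#'   \code{counts} (3 x 2 integer matrix), \code{pct_correct} (named vector
#'   for the \code{">"} and \code{"<"} strata; \code{NA} when a stratum is
#'   empty) and \code{n}.
#' @examples
#' # 10 datasets where the concatenated support is usually the better guide
#' sc <- support_comparison(c(80, 75, 90, 60, 55, 40, 30, 85, 20, 65),
#'                          c(70, 80, 85, 65, 50, 45, 35, 80, 25, 60),
#'                          c(TRUE, TRUE, TRUE, FALSE, TRUE,
#'                            FALSE, FALSE, TRUE, FALSE, TRUE))
#' sc$pct_correct
#' @export
support_comparison <- function(support_a, support_b, matches_reference,
                               cutoff = NULL, side = c("above", "below")) {
  n <- length(support_a)
  if (length(support_b) != n || length(matches_reference) != n)
    stop("inputs differ in length")
  if (any(support_a < 0 | support_a > 100 | support_b < 0 | support_b > 100))
    stop("supports must lie in [0, 100]")
  matches_reference <- as.logical(matches_reference)
  if (!is.null(cutoff)) {
    side <- match.arg(side)
    keep <- if (side == "above") support_a > cutoff & support_b > cutoff
            else support_a <= cutoff & support_b <= cutoff
    support_a <- support_a[keep]; support_b <- support_b[keep]
    matches_reference <- matches_reference[keep]
  }
  stratum <- factor(sign(support_a - support_b), levels = c(1, 0, -1),
                    labels = c(">", "=", "<"))
  match_f <- factor(matches_reference, levels = c(TRUE, FALSE),
                    labels = c("match", "mismatch"))
  counts <- table(stratum, match_f)
  pct <- function(s) {
    tot <- sum(counts[s, ])
    if (tot == 0) NA_real_ else 100 * counts[s, "match"] / tot
  }
  structure(list(counts = unclass(counts),
                 pct_correct = c(">" = pct(">"), "<" = pct("<")),
                 n = length(support_a)),
            class = "support_comparison")
}

#' @export
print.support_comparison <- function(x, ...) {
  cat("Support comparison over", x$n, "datasets\n")
  print(x$counts)
  cat(sprintf("  %% correct when a > b: %s\n",
              ifelse(is.na(x$pct_correct[">"]), "NA",
                     sprintf("%.1f%%", x$pct_correct[">"]))))
  cat(sprintf("  %% correct when a < b: %s\n",
              ifelse(is.na(x$pct_correct["<"]), "NA",
                     sprintf("%.1f%%", x$pct_correct["<"]))))
  invisible(x)
}

#' Topological correctness above and below a support threshold
#'
#' Splits datasets at a bootstrap cutoff and reports the percentage of
#' topologically correct trees in each half — the "how trustworthy is a
#' support above S" readout.
#'
#' @param support numeric supports in \code{[0, 100]}.
#' @param matches_reference logical correctness flags.
#' @param cutoff threshold; "above" means strictly greater.
#' @return list with \code{above}, \code{n_above}, \code{below},
#'   \code{n_below}; percentages are \code{NA} for empty halves.
#' @export
correctness_by_threshold <- function(support, matches_reference, cutoff = 60) {
  if (length(support) != length(matches_reference))
    stop("inputs differ in length")
  matches_reference <- as.logical(matches_reference)
  hi <- support > cutoff
  pct <- function(m) if (length(m) == 0) NA_real_ else 100 * mean(m)
  list(above = pct(matches_reference[hi]), n_above = sum(hi),
       below = pct(matches_reference[!hi]), n_below = sum(!hi))
}
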