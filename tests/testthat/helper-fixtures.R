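# Shared fixtures and independent oracles for the test suite.

# Hand-constructed triple: A and B identical, C aligns nothing like them.
# Eq-style arithmetic gives raw weights (50, 50, 100) -> normalised (25, 25, 50).
toy_triple <- function() {
  a <- msa(c(s1 = "AAA--", s2 = "-CCC-", s3 = "--GGG"), label = "A")
  b <- msa(a$chars, label = "B")
  c <- msa(c(s1 = "--AAA", s2 = "CCC--", s3 = "-GGG-"), label = "C")
  list(a, b, c)
}

# Random gapped realignment of fixed sequences: choose an alignment width and
# scatter each row's residues over it; all-gap columns are dropped.
random_gapped_msa <- function(seqs, extra = 3, label = "rnd") {
  L <- max(nchar(seqs)) + sample(0:extra, 1)
  m <- matrix("-", length(seqs), L, dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[[i]], "")[[1]]
    m[i, sort(sample.int(L, length(res)))] <- res
  }
  keep <- colSums(m != "-") > 0
  msa(m[, keep, drop = FALSE], label = label)
}

random_sequences <- function(n_taxa, min_len = 3, max_len = 6) {
  setNames(
    vapply(seq_len(n_taxa), function(i)
      paste(sample(LETTERS[1:20], sample(min_len:max_len, 1), replace = TRUE),
            collapse = ""), character(1)),
    paste0("t", seq_len(n_taxa)))
}

# Independent ColumnSim oracle: compares every column of x against every
# column of y by direct residue-occurrence counting on the row strings,
# without the package's fingerprint machinery.
brute_force_column_sim <- function(x, y) {
  ordinal <- function(m, i, j) {
    if (m$chars[i, j] == "-") return(NA_integer_)
    sum(m$chars[i, seq_len(j - 1)] != "-")
  }
  col_desc <- function(m, j) {
    ids <- m$ids
    o <- vapply(seq_along(ids), function(i) ordinal(m, i, j), integer(1))
    names(o) <- ids
    o[order(names(o))]
  }
  same_col <- function(dx, dy) {
    all((is.na(dx) & is.na(dy)) | (!is.na(dx) & !is.na(dy) & dx == dy),
        na.rm = FALSE)
  }
  eligible <- function(d) sum(!is.na(d)) >= 2
  dx <- lapply(seq_len(x$length), function(j) col_desc(x, j))
  dy <- lapply(seq_len(y$length), function(j) col_desc(y, j))
  dx <- dx[vapply(dx, eligible, logical(1))]
  dy <- dy[vapply(dy, eligible, logical(1))]
  stopifnot(length(dx) > 0)
  hits <- vapply(dx, function(d)
    any(vapply(dy, function(e) isTRUE(same_col(d, e)), logical(1))),
    logical(1))
  100 * mean(hits)
}

# Independent bipartition oracle: delete each tree edge in an igraph copy and
# read the resulting two components.
igraph_splits <- function(tree) {
  tree <- ape::unroot(ape::collapse.singles(tree))
  n <- ape::Ntip(tree)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    side <- names(comp)[comp == comp[[as.character(tree$edge[e, 1])]]]
    tips <- sort(tree$tip.label[as.integer(side[as.integer(side) <= n])])
    other <- sort(setdiff(tree$tip.label, tips))
    if (length(tips) < 2 || length(other) < 2) next
    a <- paste(tips, collapse = ","); b <- paste(other, collapse = ",")
    keys <- c(keys, if (length(tips) < length(other)) a
                    else if (length(other) < length(tips)) b
                    else min(a, b))
  }
  unique(keys)
}

# Small simulated dataset: true tree, true alignment, perturbed variants.
simulated_dataset <- function(seed, n_leaves = 8, root_length = 150,
                              scale = 0.25, indel_rate = 0.03,
                              n_variants = 4, gap_shift_rate = 0.1) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- tr$edge.length * scale
  sim <- evolve_sequences(tr, root_length = root_length,
                          indel_rate = indel_rate)
  alts <- perturb_alignment(sim$alignment, n_variants = n_variants,
                            gap_shift_rate = gap_shift_rate)
  list(tree = sim$tree, truth = sim$alignment, variants = alts)
}
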