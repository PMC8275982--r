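#' Amino-acid alphabet used by the simulator
#' @export
aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Evolve sequences along a tree with a known true alignment
#'
#' A deliberately simple simulator for fixtures and method checks: a root
#' sequence is drawn uniformly from the alphabet and evolved along each branch
#' under a uniform-rate (Jukes-Cantor-type) substitution process: over a
#' branch of length \code{b} expected substitutions per site, a site changes
#' to a uniformly chosen different residue with the exact transition
#' probability \code{(1 - 1/A)(1 - exp(-A b / (A - 1)))} for alphabet size
#' \code{A}, so residue identity to the parent decays from 1 towards the
#' stationary \code{1/A} as \code{b} grows. Optional single-site insertions
#' and deletions are superimposed. Indel events are tracked in
#' a global coordinate system, so the returned alignment is the exact true
#' alignment (every column holds homologous residues).
#'
#' @param tree \code{phylo} with branch lengths and unique tip labels.
#' @param root_length number of root sites (>= 1).
#' @param alphabet character vector of residues (default the 20 amino acids).
#' @param indel_rate per-site probability, per branch, of an indel event
#'   (split evenly between insertion and deletion); in \code{[0, 1)}.
#' @param seed integer seed for reproducibility; \code{NULL} leaves the RNG
#'   state alone.
#' @return list with \code{alignment} (the true \code{msa}, label
#'   \code{"true"}) and \code{tree} (the input tree).
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
#' sim <- evolve_sequences(tr, root_length = 50, seed = 1)
#' sim$alignment$length >= 50
#' @export
evolve_sequences <- function(tree, root_length = 200, alphabet = aa_alphabet,
                             indel_rate = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (root_length < 1) stop("root_length must be >= 1")
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must be in [0, 1)")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!is.null(seed)) set.seed(as.integer(seed))

  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  A <- length(alphabet)
  tips <- vector("list", ntip)

  evolve_branch <- function(pos, res, b) {
    n <- length(pos)
    # exact transition of the uniform-rate chain: jump to another residue
    sub <- stats::runif(n) < (1 - 1 / A) * (1 - exp(-A * b / (A - 1)))
    if (any(sub)) {
      r <- match(res[sub], alphabet)
      shift <- sample.int(A - 1, sum(sub), replace = TRUE)
      res[sub] <- alphabet[((r - 1L + shift) %% A) + 1L]
    }
    if (indel_rate > 0) {
      del <- stats::runif(n) < indel_rate / 2
      pos <- pos[!del]; res <- res[!del]
      n <- length(pos)
      if (n > 0) {
        ins <- which(stats::runif(n) < indel_rate / 2)
        for (i in ins) {
          lo <- pos[i]
          hi <- if (i < length(pos)) pos[i + 1] else pos[length(pos)] + 1
          key <- lo + (hi - lo) * stats::runif(1, 0.25, 0.75)
          at <- findInterval(key, pos)
          pos <- append(pos, key, after = at)
          res <- append(res, sample(alphabet, 1), after = at)
        }
      }
    }
    list(pos = pos, res = res)
  }

  recurse <- function(node, pos, res) {
    if (node <= ntip) { tips[[node]] <<- list(pos = pos, res = res); return() }
    for (e in kids[[as.character(node)]]) {
      st <- evolve_branch(pos, res, tree$edge.length[e])
      recurse(tree$edge[e, 2], st$pos, st$res)
    }
  }
  recurse(root, as.numeric(seq_len(root_length)),
          sample(alphabet, root_length, replace = TRUE))

  empty <- vapply(tips, function(t) length(t$pos) == 0, logical(1))
  if (any(empty))
    stop("tip '", tree$tip.label[empty][1],
         "' lost every site; lower indel_rate or lengthen the root sequence")
  keys <- sort(unique(unlist(lapply(tips, `[[`, "pos"))))
  m <- matrix("-", ntip, length(keys),
              dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip))
    m[i, match(tips[[i]]$pos, keys)] <- tips[[i]]$res
  list(alignment = msa(m, label = "true"), tree = tree)
}

#' Alternative alignments by random gap-block shifts
#'
#' Derives alternative alignments of the same sequences from a reference
#' alignment by shifting maximal gap blocks one column left or right — the
#' kind of local ambiguity on which real aligners disagree. Ungapped sequences
#' are untouched, so \code{\link{check_same_sequences}} always holds; the
#' expected pairwise \code{\link{column_sim}} between variants decreases as
#' \code{gap_shift_rate} grows, and rate 0 returns exact copies. All-gap
#' columns created by colliding shifts are dropped, so variant lengths may
#' differ slightly.
#'
#' @param truth reference \code{msa}.
#' @param n_variants number of alternative alignments to produce (>= 2).
#' @param gap_shift_rate probability, per gap block and per variant, of a
#'   one-column shift; in \code{[0, 1]}.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return list of \code{n_variants} \code{msa} objects labelled
#'   \code{"variant1"}, \code{"variant2"}, ...
#' @export
perturb_alignment <- function(truth, n_variants = 5, gap_shift_rate = 0.2,
                              seed = NULL) {
  stopifnot(inherits(truth, "msa"))
  if (n_variants < 2) stop("n_variants must be >= 2")
  if (gap_shift_rate < 0 || gap_shift_rate > 1)
    stop("gap_shift_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(n_variants), function(v) {
    m <- truth$chars
    L <- ncol(m)
    for (i in seq_len(nrow(m))) {
      r <- rle(m[i, ] == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (b in which(r$values)) {
        if (stats::runif(1) >= gap_shift_rate) next
        s <- starts[b]; e <- ends[b]
        dir <- sample(c(-1L, 1L), 1)
        if (dir == -1L && s == 1) dir <- 1L
        if (dir == 1L && e == L) dir <- -1L
        if (dir == -1L && s > 1) {          # residue before block hops to its end
          m[i, e] <- m[i, s - 1]; m[i, s - 1] <- "-"
        } else if (dir == 1L && e < L) {    # residue after block hops to its start
          m[i, s] <- m[i, e + 1]; m[i, e + 1] <- "-"
        }
      }
    }
    keep <- colSums(m != "-") > 0
    msa(m[, keep, drop = FALSE], label = paste0("variant", v))
  })
}
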