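#' Bootstrap sampling plan for a Super-MSA
#'
#' Three schemes are supported. \code{sboot} is the standard bootstrap applied
#' to the whole Super-MSA: each replicate has the full concatenated length and
#' columns are drawn uniformly. \code{psboot} draws partial replicates of the
#' average source length, compensating with N times more replicates (N = number
#' of source alignments) so the total information sampled matches
#' \code{sboot}. \code{wpsboot} additionally biases column choice: the
#' probability of drawing a column is proportional to the normalised sampling
#' weight of the alignment it comes from, so columns from the most divergent
#' aligner are favoured.
#'
#' @param super a \code{super_msa}.
#' @param scheme \code{"sboot"}, \code{"psboot"} or \code{"wpsboot"}.
#' @param base_count baseline replicate number (default 100); \code{psboot}
#'   and \code{wpsboot} generate \code{N * base_count} replicates.
#' @return object of class \code{"sampling_plan"}: list with \code{scheme},
#'   \code{replicate_length}, \code{replicate_count} and
#'   \code{column_probabilities} (sums to 1).
#' @examples
#' a <- msa(c(s1 = "AC-A", s2 = "A-CA"), label = "A")
#' b <- msa(c(s1 = "ACA-", s2 = "-ACA"), label = "B")
#' make_plan(super_msa(list(a, b)), "psboot", base_count = 100)
#' @export
make_plan <- function(super, scheme = c("sboot", "psboot", "wpsboot"),
                      base_count = 100) {
  stopifnot(inherits(super, "super_msa"))
  scheme <- match.arg(scheme)
  base_count <- as.integer(base_count)
  if (is.na(base_count) || base_count < 1) stop("base_count must be >= 1")
  L <- super$alignment$length
  n_src <- length(super$source_lengths)
  mean_len <- as.integer(floor(mean(super$source_lengths) + 0.5))  # half-up
  if (scheme == "sboot") {
    len <- L; cnt <- base_count
    prob <- rep(1 / L, L)
  } else {
    len <- mean_len; cnt <- n_src * base_count
    if (scheme == "psboot") {
      prob <- rep(1 / L, L)
    } else {
      w <- super$weights$normalized[super$provenance]
      prob <- as.numeric(w / sum(w))
    }
  }
  structure(list(scheme = scheme, replicate_length = len,
                 replicate_count = cnt, column_probabilities = prob),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat("Sampling plan (", x$scheme, "): ", x$replicate_count,
      " replicates of ", x$replicate_length, " columns\n", sep = "")
  invisible(x)
}

#' Draw bootstrap replicates
#'
#' Samples column indices with replacement according to the plan's per-column
#' probabilities. Each replicate uses its own sub-seed derived from the master
#' seed, so a replicate set is reproducible and individual replicates can be
#' regenerated independently.
#'
#' @param super a \code{super_msa}.
#' @param plan a \code{sampling_plan} built from \code{super}.
#' @param seed integer master seed; \code{NULL} leaves the RNG state alone.
#' @return list of integer vectors of column indices (1-based), one per
#'   replicate, each of length \code{plan$replicate_length}, with attributes
#'   \code{scheme} and \code{seed}.
#' @export
draw_replicates <- function(super, plan, seed = NULL) {
  stopifnot(inherits(super, "super_msa"), inherits(plan, "sampling_plan"))
  L <- super$alignment$length
  if (length(plan$column_probabilities) != L)
    stop("plan does not match the Super-MSA (", length(plan$column_probabilities),
         " probabilities for ", L, " columns)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, plan$replicate_count)
  reps <- lapply(seq_len(plan$replicate_count), function(i) {
    set.seed(sub_seeds[i])
    sample.int(L, plan$replicate_length, replace = TRUE,
               prob = plan$column_probabilities)
  })
  attr(reps, "scheme") <- plan$scheme
  attr(reps, "seed") <- seed
  reps
}

#' Materialise a replicate as an alignment
#'
#' @param super a \code{super_msa}.
#' @param rep integer vector of column indices (one replicate).
#' @param label label for the resulting alignment.
#' @return an \code{msa} whose j-th column is Super-MSA column \code{rep[j]};
#'   row order preserved.
#' @export
materialize <- function(super, rep, label = "replicate") {
  stopifnot(inherits(super, "super_msa"))
  subset_columns(super$alignment, rep, label = label)
}
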