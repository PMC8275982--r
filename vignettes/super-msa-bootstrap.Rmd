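---
title: "Alignment-uncertainty-aware bootstrap support with superboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-uncertainty-aware bootstrap support with superboot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superboot)
```

## The problem

The Felsenstein bootstrap resamples alignment columns to measure how stable a
phylogenetic tree is under sampling variation of sites. It takes the
alignment itself as given. In practice different aligners frequently disagree
about where gaps go, and trees inferred from those alternative alignments can
differ; a clade may look rock-solid under resampling of one alignment yet
vanish when the sequences are realigned. A bootstrap value that ignores this
alignment uncertainty is an overconfident one.

`superboot` folds alignment uncertainty into the bootstrap. Several
alternative multiple sequence alignments (MSAs) of the *same* sequences —
typically the outputs of different aligners — are concatenated column-wise
into a **Super-MSA**, and bootstrap replicates are drawn from the
concatenation. Three sampling schemes are provided:

* **SBOOT** — the standard bootstrap applied to the whole Super-MSA: each
  replicate draws as many columns, uniformly with replacement, as the full
  concatenated length. Simple, but columns from the N stacked alignments are
  not independent (they describe the same residues), which inflates supports.
* **pSBOOT** — *partial* super bootstrap: replicates have the average source
  length, and N times as many replicates are drawn to sample the same total
  amount of information. Supports return to the scale of a single-aligner
  bootstrap.
* **wpSBOOT** — *weighted* partial super bootstrap: like pSBOOT, but each
  column is drawn with probability proportional to the sampling weight of the
  alignment it comes from, so aligners that produce output unlike anyone
  else's contribute more, and redundant near-duplicates less.

## Column identity and the sampling weights

The weights need a notion of two columns, in two different gappings of the
same sequences, being "the same column". Column position is meaningless
across alignments, so `superboot` identifies a column by its
**residue-ordinal fingerprint**: for every taxon that is not gapped in the
column, the fingerprint records which occurrence (0-based, counting non-gap
characters from the start of the row) of that taxon's sequence sits there.
Two columns are identically aligned exactly when their fingerprints are
equal. Columns with fewer than two residues are excluded from matching on
both sides — a lone residue is not aligned *with* anything. This definition
is the package's own operationalisation of column identity; exact agreement
with any particular alignment-comparison program is not guaranteed.

The directional column similarity is

$$\mathrm{ColumnSim}(x, y) = 100 \cdot
  \frac{\#\{\text{eligible columns of } x \text{ whose fingerprint occurs in } y\}}
       {\#\{\text{eligible columns of } x\}},$$

and each alignment's raw weight is its *dissimilarity* from the rest,

$$w_x = 100 - \frac{1}{N-1} \sum_{y \neq x} \mathrm{ColumnSim}(x, y),$$

normalised to sum to 100. When every alternative alignment is identical all
raw weights are zero and the normalisation is undefined; `superboot` then
falls back to uniform weights, which makes weighted sampling collapse to the
standard bootstrap — identical alternatives should change nothing.

```{r weights}
a <- msa(c(s1 = "AAA--", s2 = "-CCC-", s3 = "--GGG"), label = "A")
b <- msa(a$chars, label = "B")              # identical twin of A
c <- msa(c(s1 = "--AAA", s2 = "CCC--", s3 = "-GGG-"), label = "C")
compute_sample_weights(list(a, b, c))       # raw (50, 50, 100) -> (25, 25, 50)
```

## Support measures

Supports are measured at two levels against a reference tree (by default
inferred from the Super-MSA itself):

* **whole-topology support** — the fraction of replicate trees whose
  non-trivial bipartition set equals the reference's (unrooted
  Robinson–Foulds distance zero);
* **clade support** — for each non-trivial bipartition of the reference, the
  fraction of replicate trees containing it.

All comparison is unrooted: a bipartition is a property of an unrooted tree,
so rooted inputs are unrooted on parse. Bipartitions are canonicalised as the
smaller side of the split (size ties broken lexicographically). Polytomous
replicate trees are allowed — a polytomy simply asserts fewer bipartitions,
so it can still support a clade but never counts as topologically identical
to a fully resolved reference.

```{r fit}
tr <- parse_newick("((A:.2,B:.2):.15,((C:.2,D:.2):.15,(E:.2,F:.2):.15):.1,(G:.2,H:.2):.15);")
sim <- evolve_sequences(tr, root_length = 150, indel_rate = 0.04, seed = 10)
alts <- perturb_alignment(sim$alignment, n_variants = 4,
                          gap_shift_rate = 0.2, seed = 11)
fit <- superboot(alts, scheme = "wpsboot", base_count = 50, seed = 12)
fit
```

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `scheme` | `superboot()` | `"wpsboot"` | sampling scheme (see above) |
| `base_count` | `superboot()` | 100 | replicates for SBOOT; pSBOOT/wpSBOOT draw `N * base_count` |
| `tree_fun` | `superboot()` | `nj_tree` | per-replicate tree inference |
| `S` | `reduce_tree()` | — | support threshold in percent; edges with support strictly below `S` are collapsed |
| `root_length` | `evolve_sequences()` | 200 | sites in the simulated root sequence |
| `indel_rate` | `evolve_sequences()` | 0 | per-site, per-branch probability of a single-site indel |
| `n_variants`, `gap_shift_rate` | `perturb_alignment()` | 5, 0.2 | number of derived alignments and per-gap-block shift probability |

The pSBOOT/wpSBOOT replicate length is the arithmetic mean of the source
lengths rounded half-up, and the replicate multiplier is exactly N, the
number of sources (seven aligners of average length 150 give a Super-MSA of
1050 columns and 700 partial replicates at `base_count = 100`). wpSBOOT
draws columns in one stage, flat weight-proportionally across the whole
Super-MSA — with equal source lengths this coincides with first choosing a
source by weight and then a column uniformly inside it; with unequal lengths
a longer divergent alignment contributes proportionally more columns, which
is the documented behaviour.

## Tree inference

`nj_tree()` is the built-in inference engine: neighbor joining (via
\pkg{ape}) on p-distances with pairwise gap deletion and no multiple-hit
correction. It is deterministic, fast, and consistent on additive distances —
exactly what replicate-level inference in tests and simulations needs — but
it is not publication-grade. For real analyses wrap a maximum-likelihood
program with `infer_external()`, which shells out with `{input}`/`{output}`
placeholders and parses the resulting newick, and pass the wrapper as
`tree_fun`.

## Evaluating bootstrap calibration

Given a known true tree, the package provides the standard decision-theoretic
toolkit for asking *how informative* a support value is:

* `all_or_nothing()` — loss 0/1 on exact topology identity;
* `rf_decompose()` — the Robinson–Foulds distance split into Type I error
  `e1` (clades asserted by the estimate but false) and Type II error `e2`
  (true clades missed);
* `reduce_tree()` — collapses every edge with support strictly below a
  threshold `S`; raising `S` can only shrink `e1` and grow `e2`, tracing the
  FP/FN trade-off;
* `ranking_curve()` / `tp_at_fp()` — sort datasets by support and count true
  positives within a false-positive budget; tied scores are consumed as
  whole blocks so the count cannot depend on input order;
* `auc()` — the rank (Mann–Whitney) form of the ROC area,
  $P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$, which handles ties exactly, unlike
  trapezoid integration over an arbitrary tie ordering;
* `support_comparison()` / `correctness_by_threshold()` — contingency
  analysis of two support readouts (e.g. wpSBOOT versus the single-aligner
  average) against topological correctness.

```{r eval}
d <- rf_decompose(fit$reference, sim$tree)
d
reduced <- reduce_tree(fit$reference, fit$clade_supports, S = 95)
rf_decompose(reduced$tree, sim$tree)
```

## What the simulator does and does not emulate

`evolve_sequences()` draws a uniform root sequence and evolves it along the
tree under a uniform-rate Markov substitution process: across a branch of
length $b$ (expected substitutions per site) a site changes to a uniformly
chosen different residue with the exact transition probability
$(1 - 1/A)(1 - e^{-Ab/(A-1)})$ for alphabet size $A$, so parent–child
identity decays from 1 to the stationary $1/A$. Single-site insertions and
deletions are superimposed at `indel_rate`, tracked in a global coordinate
system so the returned alignment is exactly the true homology.
`perturb_alignment()` then derives alternative alignments by shifting gap
blocks one column left or right, mimicking the local ambiguity real aligners
disagree about while provably preserving the ungapped sequences.

This is a fixture generator, not a realistic evolution model: there is no
rate heterogeneity across sites, no empirical substitution matrix, no
multi-residue or length-distributed indels, and perturbation touches only
gap placement, not alignment error in residue pairing. Passing tests on this
generator demonstrate that the machinery — weights, sampling laws,
support bookkeeping, error decomposition — behaves as specified; they do not
certify performance on real data produced by real aligners.

## Numerical choices and degenerate inputs

* Threshold semantics in `reduce_tree()` are strict: an edge with support
  exactly `S` survives.
* Replicate draws derive one sub-seed per replicate from the master seed, so
  replicate sets are reproducible and individual replicates re-derivable.
* Gap symbols `.` and lowercase residues are normalised on read; all-gap
  columns and all-gap rows are validation errors.
* Alignments whose sequences differ, single-alignment "concatenations", and
  leaf-set mismatches between trees are errors, not silent coercions.
* A pair of sequences with no jointly non-gap site has no defined p-distance
  and raises an error rather than an arbitrary value.

The test-suite simulations run at desk scale by design — 6–8 taxa, 80–150
root sites, 3–7 alternative alignments, 100–700 replicates, around twenty
simulated datasets for the discrimination and error-trade-off studies —
sizes chosen so the full suite exercises every claim in minutes while
leaving the statistical checks (binomial 3-sigma bands, chi-square at
p > 0.001, a paired sign test at p < 0.05) properly powered.

## Known limitations

* The built-in inference is distance-based; supports computed with `nj_tree`
  on hard alignments will differ from ML-based supports.
* ColumnSim parity with external alignment-comparison tools is not
  guaranteed (fingerprint definition above).
* Only the unweighted ($\lambda = 1$) Robinson–Foulds decomposition is
  provided; normalised or branch-length-weighted variants are out of scope.
* Site-pattern compression is not implemented; very long Super-MSAs pay the
  full per-replicate inference cost.
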