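test_that("newick parsing, bipartition extraction and canonical form", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(ape::Ntip(tr), 4)
  b <- bipartitions(tr)
  expect_length(b, 1)
  expect_identical(b[[1]], c("A", "B"))

  # caterpillar: splits {D,E} and {C,D,E} (canonical small side {A,B})
  tr2 <- parse_newick("(A,B,(C,(D,E)));")
  expect_setequal(names(bipartitions(tr2)), c("D,E", "A,B"))

  # fully resolved unrooted n-leaf tree has n - 3 internal edges
  set.seed(1)
  for (n in c(5, 7, 10)) {
    rt <- ape::rtree(n, rooted = FALSE)
    expect_length(bipartitions(rt), n - 3)
  }

  expect_length(bipartitions(parse_newick("(A,B,C,D,E);")), 0)  # star
  expect_error(parse_newick("((A,B)"), "malformed")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
})

test_that("round-trip through newick preserves topology, labels and lengths", {
  txt <- "((A:0.1,B:0.2)90:0.05,(C:0.3,D:0.4)80:0.06,E:0.5);"
  tr <- parse_newick(txt)
  back <- parse_newick(write_newick(tr))
  expect_setequal(names(bipartitions(back)), names(bipartitions(tr)))
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  expect_setequal(setdiff(back$node.label, ""), c("90", "80"))
})

test_that("a rooted input and its unrooted form give the same bipartitions", {
  rooted <- parse_newick("(((A,B),(C,D)),(E,F));")
  rerooted <- ape::root(rooted, outgroup = "A", resolve.root = TRUE)
  expect_setequal(names(bipartitions(rooted)), names(bipartitions(rerooted)))
})

test_that("topology support counts replicates with identical unrooted topology", {
  ref <- parse_newick("((A,B),(C,(D,E)));")
  same <- parse_newick("((D,E),(C,(A,B)));")   # same unrooted topology
  nni <- parse_newick("((A,C),(B,(D,E)));")
  expect_equal(topology_support(ref, list(same, same, same)), 1)
  expect_equal(topology_support(ref, list(same, same, same, nni)), 0.75)
  star <- parse_newick("(A,B,C,D,E);")
  expect_equal(topology_support(ref, list(star)), 0)  # polytomy never matches
  expect_error(topology_support(ref, list()), "empty")
  bad <- parse_newick("((A,B),(C,(D,F)));")
  expect_error(topology_support(ref, list(bad)), "missing: E")
})

test_that("clade supports count bipartition occurrences across replicates", {
  ref <- parse_newick("((A,B),(C,(D,E)));")
  nni <- parse_newick("((A,C),(B,(D,E)));")
  reps <- c(rep(list(ref), 7), rep(list(nni), 3))
  rep_out <- clade_supports(ref, reps)
  expect_s3_class(rep_out, "support_report")
  expect_equal(rep_out$replicate_count, 10)
  expect_equal(rep_out$clade_supports[["A,B"]], 0.7)
  expect_equal(rep_out$clade_supports[["D,E"]], 1.0)
  expect_equal(rep_out$tree_support, 0.7)

  # support monotonicity: appending a copy of the reference never lowers support
  more <- clade_supports(ref, c(reps, list(ref)))
  expect_true(all(more$clade_supports >= rep_out$clade_supports - 1e-12))

  # a reference clade absent from every replicate scores 0
  other <- parse_newick("((A,D),(B,(C,E)));")
  expect_equal(clade_supports(ref, list(other))$clade_supports[["A,B"]], 0)
})

test_that("split frequencies tabulate every observed bipartition", {
  t1 <- parse_newick("((A,B),(C,(D,E)));")
  t2 <- parse_newick("((A,C),(B,(D,E)));")
  f <- split_frequencies(list(t1, t1, t2))
  expect_equal(f[["D,E"]], 1)
  expect_equal(f[["A,B"]], 2 / 3)
  expect_equal(f[["A,C"]], 1 / 3)
})

test_that("neighbor joining recovers the generating topology", {
  # exactly additive distances: NJ is consistent, so the topology must match;
  # here via low-divergence simulated sequences on a known 8-leaf tree
  set.seed(3)
  tr <- ape::rtree(8, rooted = FALSE)
  tr$edge.length <- pmax(tr$edge.length * 0.15, 0.02)
  sim <- evolve_sequences(tr, root_length = 400, indel_rate = 0, seed = 4)
  est <- nj_tree(sim$alignment)
  expect_equal(rf_decompose(est, tr)$rf, 0)
  # determinism
  expect_identical(write_newick(est), write_newick(nj_tree(sim$alignment)))

  small <- msa(c(a = "AAAA", b = "AACA", c = "ACCA"))
  expect_error(nj_tree(small), "at least 4")
  nogap <- msa(c(a = "AA--", b = "AC--", c = "--GA", d = "--GG"))
  expect_error(p_distance(nogap), "no jointly non-gap site")
})

test_that("external inference adapter runs a command and parses its tree", {
  aln <- msa(c(A = "ACGT", B = "ACGA", C = "AGGA", D = "TGGA"))
  tmpl <- "printf '((A,B),(C,D));' > {output} < {input}"
  tr <- infer_external(aln, tmpl)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_match(attr(tr, "command"), "printf")

  expect_error(infer_external(aln, "no placeholders"), "placeholder")
  expect_error(infer_external(aln, "definitely-not-a-command {input} {output}"))
  expect_error(infer_external(aln, "true {input} {output}"), "no output tree")
})
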