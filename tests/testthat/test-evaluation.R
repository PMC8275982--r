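test_that("all-or-nothing loss ignores branch lengths, flags any difference", {
  t1 <- parse_newick("((A:1,B:2):1,(C:3,(D:1,E:1):2):1);")
  t2 <- parse_newick("((A:9,B:1):4,(C:1,(D:2,E:3):1):1);")
  nni <- parse_newick("((A,C),(B,(D,E)));")
  expect_equal(all_or_nothing(t1, t2), 0L)
  expect_equal(all_or_nothing(nni, t1), 1L)
  bad <- parse_newick("((A,B),(C,(D,F)));")
  expect_error(all_or_nothing(bad, t1), "missing")
  # consistency with the RF decomposition
  expect_equal(all_or_nothing(nni, t1) == 0L, rf_decompose(nni, t1)$rf == 0)
})

test_that("RF decomposition: identical, one-NNI, star, symmetry", {
  t1 <- parse_newick("((A,B),(C,(D,E)));")
  expect_equal(unclass(rf_decompose(t1, t1))[c("e1", "e2", "rf")],
               list(e1 = 0L, e2 = 0L, rf = 0L))
  nni <- parse_newick("((A,C),(B,(D,E)));")
  d <- rf_decompose(nni, t1)
  expect_equal(c(d$e1, d$e2, d$rf), c(1, 1, 2))
  # swapping arguments exchanges e1 and e2
  d2 <- rf_decompose(t1, nni)
  expect_equal(c(d2$e1, d2$e2), c(d$e2, d$e1))
  # a star estimate asserts nothing: e1 = 0, e2 = n - 3
  star <- parse_newick("(A,B,C,D,E);")
  ds <- rf_decompose(star, t1)
  expect_equal(c(ds$e1, ds$e2, ds$rf), c(0, 2, 2))
})

test_that("RF decomposition matches independent oracles on random tree pairs", {
  skip_if_not_installed("igraph")
  skip_if_not_installed("phangorn")
  set.seed(99)
  for (k in 1:40) {
    n <- sample(4:8, 1)
    t1 <- ape::rtree(n, rooted = FALSE)
    t2 <- ape::rtree(n, rooted = FALSE)
    t2$tip.label <- sample(t1$tip.label)
    d <- rf_decompose(t1, t2)
    s1 <- igraph_splits(t1); s2 <- igraph_splits(t2)
    expect_equal(d$e1, length(setdiff(s1, s2)), info = paste("pair", k))
    expect_equal(d$e2, length(setdiff(s2, s1)), info = paste("pair", k))
    expect_equal(d$rf, phangorn::RF.dist(t1, t2), info = paste("pair", k))
  }
})

test_that("tree reduction collapses exactly the edges below threshold", {
  tr <- parse_newick("(((A,B),C),((D,E),F));")
  keys <- names(bipartitions(tr))
  sup <- setNames(rep(1, length(keys)), keys)

  # all supports 100: unchanged at any threshold
  r <- reduce_tree(tr, sup, 100)
  expect_setequal(names(bipartitions(r$tree)), keys)

  # one edge at 49% with S = 50: that edge collapses into a polytomy
  sup2 <- sup; sup2[["A,B,C"]] <- 0.49
  r2 <- reduce_tree(tr, sup2, 50)
  expect_setequal(names(bipartitions(r2$tree)), setdiff(keys, "A,B,C"))
  expect_identical(sort(r2$tree$tip.label), sort(tr$tip.label))

  # strict-less-than semantics: support exactly S survives
  sup3 <- sup; sup3[["A,B,C"]] <- 0.50
  r3 <- reduce_tree(tr, sup3, 50)
  expect_setequal(names(bipartitions(r3$tree)), keys)

  # S = 0 never removes anything
  r0 <- reduce_tree(tr, sup2, 0)
  expect_setequal(names(bipartitions(r0$tree)), keys)

  expect_error(reduce_tree(tr, sup[-1], 50), "no support value")
  expect_error(reduce_tree(tr, sup, 101), "percentage")
})

test_that("raising the reduction threshold trades Type I for Type II error", {
  set.seed(17)
  truth <- ape::rtree(8, rooted = FALSE)
  est <- ape::rtree(8, rooted = FALSE)
  est$tip.label <- sample(truth$tip.label)
  keys <- names(bipartitions(est))
  sup <- setNames(runif(length(keys)), keys)
  prev <- NULL
  for (S in c(0, 25, 50, 75, 95)) {
    d <- rf_decompose(reduce_tree(est, sup, S)$tree, truth)
    if (!is.null(prev)) {
      expect_lte(d$e1, prev$e1)
      expect_gte(d$e2, prev$e2)
    }
    prev <- d
  }
})

test_that("ranking curve walks tie blocks and honours the FP budget", {
  cv <- ranking_curve(c(9, 8, 7, 6, 5), c(1, 1, 0, 1, 0))
  expect_equal(tp_at_fp(cv, 1), 3)
  expect_equal(tp_at_fp(cv, 0), 2)
  expect_true(all(diff(cv$fp) >= 0) && all(diff(cv$tp) >= 0))
  expect_equal(unlist(cv[nrow(cv), c("fp", "tp")], use.names = FALSE), c(2, 3))

  # perfect separation: every positive before any negative
  cv2 <- ranking_curve(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))
  expect_equal(tp_at_fp(cv2, 0), 3)

  # all scores tied: one block, admitted whole or not at all
  cv3 <- ranking_curve(rep(1, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(nrow(cv3), 1)
  expect_equal(tp_at_fp(cv3, 2), 0)
  expect_equal(tp_at_fp(cv3, 3), 3)

  # budget monotone; at budget = negatives it reaches all positives
  budgets <- 0:2
  tps <- vapply(budgets, function(b) tp_at_fp(cv, b), numeric(1))
  expect_true(all(diff(tps) >= 0))
  expect_equal(tp_at_fp(cv, 2), 3)

  expect_error(ranking_curve(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("rank-based AUC handles ties and matches an independent ROC package", {
  expect_equal(auc(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0)), 1)
  expect_equal(auc(c(3, 2, 1), c(1, 0, 1)), 0.5)
  set.seed(21)
  scores <- rnorm(40); labels <- rep(c(TRUE, FALSE), 20)
  expect_equal(auc(scores, labels) + auc(scores, !labels), 1)
  skip_if_not_installed("pROC")
  for (k in 1:10) {
    s <- sample(1:6, 30, replace = TRUE)   # plenty of ties
    l <- runif(30) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(auc(s, l),
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 info = paste("case", k))
  }
})

test_that("support comparison stratifies by support sign and correctness", {
  a <- c(80, 75, 90, 60, 50, 40, 70, 70)
  b <- c(70, 80, 85, 65, 55, 45, 70, 70)
  m <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  sc <- support_comparison(a, b, m)
  expect_equal(sum(sc$counts), 8)
  expect_equal(unname(sc$counts[">", "match"]), 2)       # 80>70 T, 90>85 T
  expect_equal(unname(sc$pct_correct[">"]), 100)
  expect_equal(unname(sc$pct_correct["<"]), 50)          # 75<80 T, 60<65 F, 50<55 F, 40<45 T

  # cutoff restriction keeps only datasets with both supports above it
  sc_hi <- support_comparison(a, b, m, cutoff = 60, side = "above")
  expect_equal(sc_hi$n, 5)

  # an empty stratum reports NA, not a crash
  sc_gt <- support_comparison(c(10, 20), c(5, 15), c(TRUE, FALSE))
  expect_true(is.na(sc_gt$pct_correct["<"]))

  expect_error(support_comparison(c(101, 2), c(1, 2), c(TRUE, TRUE)), "0, 100")
})

test_that("correctness splits cleanly at a bootstrap cutoff", {
  out <- correctness_by_threshold(c(90, 80, 70, 50, 30),
                                  c(TRUE, TRUE, FALSE, FALSE, TRUE), cutoff = 60)
  expect_equal(out$n_above, 3)
  expect_equal(out$above, 100 * 2 / 3)
  expect_equal(out$below, 50)
  empty <- correctness_by_threshold(c(10, 20), c(TRUE, TRUE), cutoff = 60)
  expect_true(is.na(empty$above))
})
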