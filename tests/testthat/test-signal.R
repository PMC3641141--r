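test_that("sankoff score recovers trivial parsimony lengths", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  expect_equal(sankoff_score(tr, c(a = "x", b = "x", c = "x", d = "x")), 0)
  expect_equal(sankoff_score(tr, c(a = "x", b = "x", c = "y", d = "y")), 1)
  expect_equal(sankoff_score(tr, c(a = "x", b = "y", c = "x", d = "y")), 2)
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(sankoff_score(two, c(a = "p", b = "q")), 1)
  badcost <- matrix(0, 2, 2, dimnames = list(c("x", "z"), c("x", "z")))
  expect_error(sankoff_score(tr, c(a = "x", b = "x", c = "y", d = "y"),
                             cost = badcost),
               "not in the cost matrix")
})

test_that("sankoff equals exhaustive enumeration on 8-tip 3-state traits", {
  states <- c("A", "R", "N")
  cost <- 1 - diag(3)
  dimnames(cost) <- list(states, states)
  for (s in 1:3) {
    set.seed(s * 7)
    tr <- ape::rtree(8)
    x <- setNames(sample(states, 8, replace = TRUE), tr$tip.label)
    expect_equal(sankoff_score(tr, x, cost), bf_sankoff(tr, x, states, cost))
  }
  # non-unit costs exercise the general recursion
  cost2 <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3,
                  dimnames = list(states, states))
  set.seed(99)
  tr <- ape::rtree(7)
  x <- setNames(sample(states, 7, replace = TRUE), tr$tip.label)
  expect_equal(sankoff_score(tr, x, cost2), bf_sankoff(tr, x, states, cost2))
})

test_that("sankoff handles polytomies natively", {
  tr <- ape::read.tree(text = "((a,b,c),(d,e));")
  x <- c(a = "x", b = "x", c = "y", d = "y", e = "y")
  states <- c("x", "y")
  cost <- 1 - diag(2)
  dimnames(cost) <- list(states, states)
  expect_equal(sankoff_score(tr, x, cost), bf_sankoff(tr, x, states, cost))
})

test_that("unit-cost sankoff equals Fitch parsimony length", {
  skip_if_not_installed("phangorn")
  for (s in 1:4) {
    set.seed(s * 11)
    tr <- ape::rtree(12)
    x <- setNames(sample(c("0", "1"), 12, replace = TRUE), tr$tip.label)
    dat <- phangorn::phyDat(matrix(x, ncol = 1,
                                   dimnames = list(names(x), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(sankoff_score(tr, x),
                 as.numeric(phangorn::parsimony(tr, dat)))
  }
})

test_that("clade-partitioned traits show strong parsimony signal", {
  tr <- balanced_tree(16)
  x <- setNames(rep(c("acc", "rep"), each = 8), paste0("t", 1:16))
  res <- sankoff_signal_test(tr, x, n_perm = 999, seed = 1)
  expect_equal(res$score, 1)
  expect_lte(res$p, 0.01)
})

test_that("permutation p-values hit the rank-formula edge cases", {
  # one deviant tip: every permutation scores 1, so p must be 1
  tr <- balanced_tree(8)
  x <- setNames(c("a", rep("b", 7)), paste0("t", 1:8))
  res <- sankoff_signal_test(tr, x, n_perm = 199, seed = 2)
  expect_equal(res$p, 1)
  # constant trait is flagged, not scored
  res0 <- sankoff_signal_test(tr, setNames(rep("a", 8), paste0("t", 1:8)),
                              n_perm = 99)
  expect_equal(res0$flag, "degenerate_trait")
  expect_true(is.na(res0$p))
})

test_that("sankoff null p-values are roughly uniform for shuffled traits", {
  set.seed(3)
  tr <- ape::rtree(24)
  ps <- replicate(40, {
    x <- setNames(sample(rep(c("a", "b"), 12)), tr$tip.label)
    sankoff_signal_test(tr, x, n_perm = 99)$p
  })
  expect_gt(mean(ps), 0.3)          # no systematic excess of small p
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("the d-sum matches a hand-worked nodal averaging example", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  # states a=1,b=0,c=0,d=0: nodal means 0.5 and 0, root contrast |0.5-0|
  d <- fritz_purvis_d(tr, c(a = 1, b = 0, c = 0, d = 0), n_perm = 20,
                      seed = 1)
  expect_equal(d$d_obs, 1 + 0 + 0.5)
})

test_that("a trait confined to one deep clade gives D below zero", {
  tr <- balanced_tree(32)
  x <- setNames(as.numeric(seq_len(32) <= 8), paste0("t", 1:32))
  d <- fritz_purvis_d(tr, x, n_perm = 500, seed = 4)
  expect_equal(d$flag, "ok")
  expect_lt(d$d, 0)
  expect_lt(d$p_random, 0.05)       # far more conserved than random
})

test_that("D is invariant to the order tips are supplied in", {
  set.seed(5)
  g <- generate_tree(16, trait = "shuffle", seed = 5)
  x <- ifelse(g$trait == 1, "acc", "rep")
  x2 <- x[sample(names(x))]
  d1 <- fritz_purvis_d(g$tree, x, n_perm = 100, seed = 9)
  d2 <- fritz_purvis_d(g$tree, x2, n_perm = 100, seed = 9)
  expect_equal(d1$d, d2$d)
})

test_that("degenerate binary traits are flagged rather than scored", {
  g <- generate_tree(8, seed = 6)
  d <- fritz_purvis_d(g$tree, setNames(rep(1, 8), g$tree$tip.label),
                      n_perm = 50)
  expect_equal(d$flag, "degenerate_trait")
  expect_true(is.na(d$d))
  expect_error(fritz_purvis_d(g$tree,
                              setNames(c("a", "b", "c", rep("a", 5)),
                                       g$tree$tip.label)),
               "more than two states")
})
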