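test_that("forest generation is deterministic per spec seed", {
  sp <- forest_spec(window = c(0, 0, 100, 100), n_species = 5, seed = 12)
  expect_identical(generate_forest(sp)$stems, generate_forest(sp)$stems)
})

test_that("uniform abundance yields exact counts and CSR-like spread", {
  pl <- generate_forest(forest_spec(window = c(0, 0, 200, 200),
                                    n_species = 10, abundance = "uniform",
                                    stems_per_species = 100, seed = 2))
  expect_equal(unname(table(pl$stems$species)),
               rep(100, 10), ignore_attr = TRUE)
  quad <- table(cut(pl$stems$x, c(0, 100, 200)),
                cut(pl$stems$y, c(0, 100, 200)))
  expect_gt(chisq.test(as.vector(quad))$p.value, 0.001)
  expect_true(all(pl$stems$dbh >= 1))
})

test_that("log-series abundances are right-skewed positive counts", {
  pl <- generate_forest(forest_spec(window = c(0, 0, 100, 100),
                                    n_species = 40, seed = 3))
  ab <- table(pl$stems$species)
  expect_true(all(ab >= 1))
  expect_gt(mean(ab), median(ab))   # long right tail
})

test_that("thomas species cluster more than CSR", {
  pairs_within <- function(xy, r) {
    d <- as.matrix(dist(xy))
    (sum(d <= r) - nrow(xy)) / 2
  }
  sp <- forest_spec(window = c(0, 0, 200, 200), n_species = 2,
                    abundance = "uniform", stems_per_species = 80,
                    placements = list(sp001 = list(type = "thomas",
                                                   kappa = 5e-4, mu = 10,
                                                   sigma = 5)),
                    seed = 8)
  pl <- generate_forest(sp)
  st <- split(pl$stems[c("x", "y")], pl$stems$species)
  n_thomas <- pairs_within(st$sp001, 10)
  # CSR reference distribution for the same n, by simulation
  set.seed(80)
  csr <- replicate(99, pairs_within(data.frame(x = runif(80, 0, 200),
                                               y = runif(80, 0, 200)), 10))
  expect_gt(n_thomas, quantile(csr, 0.99))
  expect_lt(pairs_within(st$sp002, 10), quantile(csr, 0.99))
})

test_that("attract species are enriched near their target", {
  sp <- forest_spec(window = c(0, 0, 200, 200), n_species = 3,
                    abundance = "uniform", stems_per_species = 60,
                    placements = list(sp002 = list(type = "attract",
                                                   target = "sp001",
                                                   radius = 10,
                                                   multiplier = 10)),
                    seed = 14)
  pl <- generate_forest(sp)
  st <- split(pl$stems, pl$stems$species)
  near_target <- function(df) {
    mean(vapply(seq_len(nrow(df)), function(i)
      any((st$sp001$x - df$x[i])^2 + (st$sp001$y - df$y[i])^2 <= 100),
      logical(1)))
  }
  expect_gt(near_target(st$sp002), near_target(st$sp003) + 0.2)
  truth <- attr(pl, "truth")
  expect_equal(truth$placement[truth$species == "sp002"], "attract")
})

test_that("invalid placement specs are rejected", {
  expect_error(forest_spec(placements = list(sp001 = list(
    type = "attract", target = "sp001", radius = 10, multiplier = 5))),
    "another species")
  expect_error(forest_spec(placements = list(sp001 = list(
    type = "attract", target = "sp002", radius = 150, multiplier = 5))),
    "effect radius")
  expect_error(forest_spec(placements = list(sp001 = list(
    type = "nope"))), "unknown placement type")
})

test_that("simulated trees have exact tip counts, prevalence and depth", {
  g <- generate_tree(64, trait = "shuffle", prevalence = 0.5, seed = 10)
  expect_equal(length(g$tree$tip.label), 64)
  expect_equal(sum(g$trait), 32)
  depths <- ape::node.depth.edgelength(g$tree)[1:64]
  expect_lt(diff(range(depths)), 1e-8)   # ultrametric Yule tree
  g2 <- generate_tree(20, trait = "brownian_threshold", prevalence = 0.25,
                      seed = 11)
  expect_equal(sum(g2$trait), 5)
  expect_identical(generate_tree(10, seed = 4)$tree,
                   generate_tree(10, seed = 4)$tree)
})

test_that("brownian-threshold traits carry more signal than shuffled ones", {
  set.seed(20)
  score <- function(kind) {
    g <- generate_tree(32, trait = kind, prevalence = 0.5)
    sankoff_score(g$tree, setNames(as.character(g$trait),
                                   names(g$trait)))
  }
  bm <- replicate(25, score("brownian_threshold"))
  sh <- replicate(25, score("shuffle"))
  expect_lt(mean(bm), mean(sh))   # fewer changes: phylogenetic signal
})
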