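ipar_fixture <- function() {
  pl <- generate_forest(forest_spec(window = c(0, 0, 120, 120), n_species = 6,
                                    abundance = "uniform",
                                    stems_per_species = 25, seed = 17))
  tr <- generate_tree(6, tip_labels = sort(unique(pl$stems$species)),
                      seed = 17)$tree
  list(plot = pl, tree = tr)
}

test_that("neighborhood PD handles empty and pair neighborhoods", {
  st <- data.frame(stem_id = c("f", "a", "b"),
                   species = c("foc", "spA", "spB"),
                   x = c(60, 63, 60), y = c(60, 60, 64), dbh = 1)
  pl <- census_plot(st, c(0, 0, 120, 120))
  tr <- ape::read.tree(text = "((foc:1,spA:1):1,(spB:1.5,spX:1.5):0.5);")
  suppressMessages({
    obs <- ipar_observed(pl, tr, "foc", radii = c(1, 5), buffer = 30)
  })
  expect_equal(obs$obs_pd[1], 0)                       # nothing within 1 m
  expect_equal(obs$n_empty[1], 1)
  # both heterospecifics within 5 m: PD of {spA, spB} on the pruned tree
  pruned <- ape::keep.tip(tr, c("foc", "spA", "spB"))
  expect_equal(obs$obs_pd[2], bf_pd(pruned, c("spA", "spB")))
})

test_that("observed IPAR equals per-focal brute-force recomputation", {
  fx <- ipar_fixture()
  sp <- "sp003"
  suppressMessages(
    obs <- ipar_observed(fx$plot, fx$tree, sp, radii = c(5, 12, 30),
                         buffer = 30))
  foc <- eligible_focals(fx$plot, sp, 30)
  for (j in seq_along(c(5, 12, 30))) {
    r <- c(5, 12, 30)[j]
    pds <- vapply(foc$stem_id, function(id) {
      nb <- bf_neighborhood(fx$plot, id, r)
      if (!length(nb)) 0 else bf_pd(fx$tree, nb)
    }, numeric(1))
    expect_equal(obs$obs_pd[j], mean(pds))
  }
})

test_that("exhaustive tip-shuffle null matches direct enumeration", {
  st <- data.frame(
    stem_id = c("f1", "a", "b", "c"),
    species = c("foc", "spA", "spB", "spC"),
    x = c(60, 62, 60, 80), y = c(60, 60, 63, 95), dbh = 1)
  pl <- census_plot(st, c(0, 0, 120, 120))
  tr <- ape::read.tree(
    text = "((foc:1,spA:1):2,(spB:2.5,spC:2.5):0.5);")
  res <- ses_pd(pl, tr, "foc", radii = c(4, 50), buffer = 30,
                method = "exhaustive")
  # oracle: enumerate all 24 relabelings of the 4 tips by hand
  tips <- tr$tip.label
  allp <- expand.grid(rep(list(1:4), 4))
  allp <- allp[apply(allp, 1, function(p) length(unique(p)) == 4), ]
  nb4 <- bf_neighborhood(pl, "f1", 4)     # spA, spB
  nb50 <- bf_neighborhood(pl, "f1", 50)   # all three
  for (j in 1:2) {
    nb <- list(nb4, nb50)[[j]]
    null <- apply(allp, 1, function(p) {
      relab <- setNames(tips[unlist(p)], tips)  # shuffled name on each tip
      bf_pd(tr, names(relab)[match(nb, relab)])
    })
    expect_equal(res$null_mean[j], mean(null))
    expect_equal(res$null_sd[j], sd(null))
    expect_equal(res$ses_pd[j],
                 (bf_pd(tr, nb) - mean(null)) / sd(null))
  }
})

test_that("extreme observed PD yields a positive ses and accumulator call", {
  set.seed(41)
  ens <- matrix(runif(999 * 2, 1, 2), 999, 2)
  attr(ens, "radii") <- c(5, 10)
  cls <- classify_status(c(3, 1.5), ens)
  expect_equal(as.character(cls$status), c("accumulator", "neutral"))
})

test_that("ses_pd centers on zero when the data are a null draw", {
  fx <- ipar_fixture()
  set.seed(42)
  vals <- replicate(25, {
    tr <- fx$tree
    tr$tip.label <- sample(tr$tip.label)
    suppressMessages(
      ses_pd(fx$plot, tr, "sp001", radii = 15, buffer = 30,
             n_shuffle = 99)$ses_pd)
  })
  expect_lt(abs(mean(vals)), 0.5)
})

test_that("per-focal standardization runs and stays finite", {
  fx <- ipar_fixture()
  suppressMessages(
    res <- ses_pd(fx$plot, fx$tree, "sp002", radii = c(10, 20), buffer = 30,
                  n_shuffle = 99, standardize = "per_focal", seed = 5))
  expect_true(all(is.finite(res$ses_pd) | res$flag != "ok"))
})

test_that("ipar binds species and skips those without eligible focals", {
  fx <- ipar_fixture()
  suppressMessages(
    res <- ipar(fx$plot, fx$tree, species = c("sp001", "sp004"),
                radii = c(10, 25), buffer = 30, n_shuffle = 99, seed = 9))
  expect_setequal(unique(res$species), c("sp001", "sp004"))
  expect_named(
    res, c("species", "radius_m", "n_focals", "obs_pd", "null_mean",
           "null_sd", "ses_pd", "status", "n_empty", "n_singleton", "flag"))
})
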