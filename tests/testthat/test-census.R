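test_that("census plot construction validates geometry and measurements", {
  st <- data.frame(stem_id = 1:2, species = c("a", "b"),
                   x = c(1, 2), y = c(1, 2), dbh = c(1, 2))
  expect_s3_class(census_plot(st, c(0, 0, 10, 10)), "census_plot")
  expect_error(census_plot(st, c(0, 0, 0, 10)), "degenerate window")
  expect_error(census_plot(transform(st, x = c(1, 11)), c(0, 0, 10, 10)),
               "outside the window")
  expect_error(census_plot(transform(st, dbh = c(1, 0)), c(0, 0, 10, 10)),
               "dbh")
  expect_error(census_plot(transform(st, stem_id = c(1, 1)), c(0, 0, 10, 10)),
               "duplicate stem_id")
  expect_error(census_plot(st[, -5], c(0, 0, 10, 10)), "lacks column")
})

test_that("duplicate coordinates for distinct stems are allowed and counted", {
  st <- data.frame(stem_id = c("a", "b", "f"), species = c("x", "x", "y"),
                   x = c(5, 5, 5), y = c(6, 6, 5), dbh = 1)
  pl <- census_plot(st, c(0, 0, 10, 10))
  expect_equal(nrow(pl$stems), 3)
  expect_setequal(neighborhood_species(pl, "f", r = 2), "x")
})

test_that("eligible focals respect the edge buffer, boundary inclusive", {
  st <- data.frame(stem_id = c("in", "out"), species = "a",
                   x = c(50, 49), y = c(50, 50), dbh = 1)
  pl <- census_plot(st, c(0, 0, 100, 100))
  foc <- eligible_focals(pl, "a", buffer = 50)
  expect_equal(foc$stem_id, "in")   # (50,50) kept, (49,50) dropped
  expect_error(eligible_focals(pl, "zz", 50), "absent")
  # present-but-all-near-edge is an empty table, not an error
  expect_equal(nrow(eligible_focals(pl, "a", buffer = 51)), 0L)
})

test_that("eligible focals equal a brute-force edge-distance scan", {
  pl <- generate_forest(forest_spec(window = c(0, 0, 300, 300),
                                    n_species = 4, abundance = "uniform",
                                    stems_per_species = 50, seed = 21))
  for (sp in unique(pl$stems$species)) {
    got <- eligible_focals(pl, sp, buffer = 50)
    expect_setequal(got$stem_id, bf_eligible(pl, sp, 50)$stem_id)
  }
})

test_that("neighborhood species obey distance, tie and exclusion rules", {
  pl <- hand_plot()
  # sole heterospecific at distance 3: in at r = 5, out at r = 2
  expect_setequal(neighborhood_species(pl, "f1", 5), c("spA", "spB"))
  expect_equal(neighborhood_species(pl, "f1", 2), character())
  # tie at exactly r is included (a2 is 8 m from f1)
  expect_true("spA" %in% neighborhood_species(pl, "f1", 8))
  # focal species never counts itself even when conspecifics are near
  expect_false("foc" %in% neighborhood_species(pl, "f1", 10))
  # with conspecifics included, the focal stem is still not its own neighbor
  nb <- neighborhood_species(pl, "f1", 2.5, exclude_focal_species = FALSE)
  expect_setequal(nb, "foc")  # f2 at distance 2, no heterospecific that close
})

test_that("neighborhood counts match an all-pairs scan on a generated plot", {
  pl <- generate_forest(forest_spec(window = c(0, 0, 150, 150),
                                    n_species = 10, abundance = "uniform",
                                    stems_per_species = 50, seed = 9))
  ids <- sample(pl$stems$stem_id, 40)
  for (id in ids) {
    for (r in c(5, 10, 25)) {
      expect_identical(sort(neighborhood_species(pl, id, r)),
                       bf_neighborhood(pl, id, r))
      expect_identical(
        sort(neighborhood_species(pl, id, r, exclude_focal_species = FALSE)),
        bf_neighborhood(pl, id, r, exclude_focal_species = FALSE))
    }
  }
})

test_that("isar curve is the mean over focals and matches recomputation", {
  pl <- hand_plot()
  # two eligible focals at buffer 40: f1 and f2
  cur <- isar_curve(pl, "foc", radii = c(2, 5, 60), buffer = 40)
  expect_equal(cur$n_focals, rep(2, 3))
  bf <- sapply(c(2, 5, 60), function(r)
    mean(c(length(bf_neighborhood(pl, "f1", r)),
           length(bf_neighborhood(pl, "f2", r)))))
  expect_equal(cur$obs_mean_richness, bf)
  expect_error(isar_curve(pl, "spC", buffer = 40), "no individual")
})

test_that("isar curves are non-decreasing and bounded by species count - 1", {
  pl <- generate_forest(forest_spec(window = c(0, 0, 150, 150),
                                    n_species = 8, abundance = "uniform",
                                    stems_per_species = 40, seed = 13))
  for (sp in c("sp001", "sp005")) {
    cur <- isar_curve(pl, sp, radii = 1:30, buffer = 30)
    expect_true(all(diff(cur$obs_mean_richness) >= 0))
    expect_true(all(cur$obs_mean_richness <= 7))
  }
})

test_that("dbh and abundance filters are monotone and tracked", {
  pl <- generate_forest(forest_spec(window = c(0, 0, 100, 100),
                                    n_species = 6, seed = 4))
  f1 <- apply_filters(pl, dbh_min = 1)
  f10 <- apply_filters(pl, dbh_min = 10)
  expect_lte(nrow(f10$stems), nrow(f1$stems))
  fab <- apply_filters(pl, abundance_min = 15)
  ab <- table(fab$stems$species)
  expect_true(all(ab >= 15))
  expect_true(all(attr(fab, "dropped")$reason == "below abundance_min"))
})
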