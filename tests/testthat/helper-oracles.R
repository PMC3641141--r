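# Independent brute-force oracles and tiny fixture builders. Everything here
# deliberately avoids the package's own engines (incidence matrices,
# compiled distance kernels) so tests compare two routes to each quantity.

# all-pairs neighborhood species scan
bf_neighborhood <- function(plot, stem_id, r, exclude_focal_species = TRUE) {
  st <- plot$stems
  i <- match(stem_id, st$stem_id)
  d <- sqrt((st$x - st$x[i])^2 + (st$y - st$y[i])^2)
  keep <- d <= r & seq_len(nrow(st)) != i
  sp <- st$species[keep]
  if (exclude_focal_species) sp <- sp[sp != st$species[i]]
  sort(unique(sp))
}

# per-stem edge-distance scan
bf_eligible <- function(plot, species, buffer) {
  st <- plot$stems[plot$stems$species == species, , drop = FALSE]
  w <- plot$window
  keep <- st$x - w["xmin"] >= buffer & w["xmax"] - st$x >= buffer &
          st$y - w["ymin"] >= buffer & w["ymax"] - st$y >= buffer
  st[keep, , drop = FALSE]
}

# Faith's PD by union of root paths, built from ape::nodepath
bf_pd <- function(tree, species, rooted = TRUE) {
  tips <- match(species, tree$tip.label)
  root <- length(tree$tip.label) + 1L
  edge_id <- function(a, b)
    which(tree$edge[, 1] == a & tree$edge[, 2] == b)
  paths <- lapply(tips, function(tp) {
    nd <- ape::nodepath(tree, root, tp)
    vapply(seq_len(length(nd) - 1L),
           function(j) edge_id(nd[j], nd[j + 1L]), integer(1))
  })
  un <- unique(unlist(paths))
  total <- sum(tree$edge.length[un])
  if (rooted) return(total)
  if (length(paths) == 1L) return(0)
  total - sum(tree$edge.length[Reduce(intersect, paths)])
}

# exact Sankoff cost by exhaustive enumeration over internal-node labelings
bf_sankoff <- function(tree, states_named, states, cost) {
  n <- length(tree$tip.label)
  n_int <- tree$Nnode
  tipstate <- match(states_named[tree$tip.label], states)
  best <- Inf
  grid <- rep(list(seq_along(states)), n_int)
  combos <- do.call(expand.grid, grid)
  for (row in seq_len(nrow(combos))) {
    lab <- c(tipstate, as.integer(combos[row, ]))
    cst <- sum(cost[cbind(lab[tree$edge[, 1]], lab[tree$edge[, 2]])])
    if (cst < best) best <- cst
  }
  best
}

# small deterministic plot laid out by hand
hand_plot <- function() {
  stems <- data.frame(
    stem_id = c("f1", "a1", "a2", "b1", "c1", "f2"),
    species = c("foc", "spA", "spA", "spB", "spC", "foc"),
    x = c(50, 50, 58, 53, 90, 52),
    y = c(50, 53, 50, 54, 90, 50),
    dbh = c(5, 2, 3, 1, 8, 1.5))
  census_plot(stems, c(0, 0, 100, 100))
}

balanced_tree <- function(n = 16) {
  tr <- ape::stree(n, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
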