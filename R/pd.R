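## Validation and root-path precomputation for ape "phylo" trees.

check_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape \"phylo\" object")
  if (is.null(tree$edge.length))
    stop("phylogeny must carry branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  if (!ape::is.rooted(tree)) stop("phylogeny must be rooted")
  invisible(tree)
}

match_tips <- function(tree, species) {
  i <- match(species, tree$tip.label)
  if (anyNA(i))
    stop("species not on the phylogeny: ",
         paste(species[is.na(i)], collapse = ", "))
  i
}

## For each tip, the edge indices on its path to the root.
root_paths <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  pedge <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  pedge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n + 1L
  lapply(seq_len(n), function(tip) {
    path <- integer()
    v <- tip
    while (v != root) {
      path <- c(path, pedge[v])
      v <- parent[v]
    }
    path
  })
}

pd_engine <- function(tree) {
  check_phylogeny(tree)
  list(paths = root_paths(tree), el = tree$edge.length,
       labels = tree$tip.label)
}

pd_from_engine <- function(eng, tip_idx, rooted = TRUE) {
  if (!length(tip_idx)) return(0)
  paths <- eng$paths[tip_idx]
  un <- unique(unlist(paths, use.names = FALSE))
  total <- sum(eng$el[un])
  if (rooted) return(total)
  if (length(tip_idx) == 1L) return(0)
  shared <- Reduce(intersect, paths)        # edges above the MRCA
  total - sum(eng$el[shared])
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting a species set.
#' Under the default rooted convention the subtree also connects the root,
#' so a singleton set returns its root-to-tip path length; with
#' `rooted = FALSE` the branch above the set's most recent common ancestor
#' is excluded and singletons return 0.
#'
#' @param tree rooted `phylo` object with branch lengths.
#' @param species character vector of tip labels (non-empty).
#' @param rooted include the path to the root (default TRUE).
#' @return Branch-length sum (scalar).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
#' faith_pd(tr, c("a", "b"))      # 3: two tip branches plus their stem
#' faith_pd(tr, tr$tip.label)     # 6: the whole tree
#' @export
faith_pd <- function(tree, species, rooted = TRUE) {
  if (!length(species)) stop("`species` must be non-empty")
  eng <- pd_engine(tree)
  pd_from_engine(eng, match_tips(tree, species), rooted)
}

mpd_from_dist <- function(D, idx) {
  d <- D[idx, idx]
  mean(d[lower.tri(d)])
}

mntd_from_dist <- function(D, idx) {
  d <- D[idx, idx]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Mean pairwise and nearest-taxon patristic distances
#'
#' Unweighted (presence-only) summaries of the patristic distances within a
#' species set: `mpd` is the mean over all unordered pairs, `mntd` the mean
#' over species of the distance to the nearest other member of the set.
#'
#' @inheritParams faith_pd
#' @param species character vector of at least two tip labels.
#' @return Scalar distance in the tree's branch-length units.
#' @export
mpd <- function(tree, species) {
  check_phylogeny(tree)
  if (length(species) < 2) stop("mpd needs at least two species")
  match_tips(tree, species)
  D <- ape::cophenetic.phylo(tree)
  mpd_from_dist(D[species, species], seq_along(species))
}

#' @rdname mpd
#' @export
mntd <- function(tree, species) {
  check_phylogeny(tree)
  if (length(species) < 2) stop("mntd needs at least two species")
  match_tips(tree, species)
  D <- ape::cophenetic.phylo(tree)
  mntd_from_dist(D[species, species], seq_along(species))
}

#' Net relatedness and nearest taxon indices
#'
#' Standardized phylogenetic dispersion of a species assemblage on a plot
#' phylogeny. The null model shuffles species names across all tips of the
#' tree (equivalently: draws equal-sized random tip sets);
#' `NRI = -(mpd_obs - mean(mpd_null)) / sd(mpd_null)` and NTI analogously
#' with mntd. Positive values indicate phylogenetic clustering (members more
#' closely related than expected), negative values overdispersion.
#'
#' @inheritParams mpd
#' @param n_shuffle number of tip-label randomizations (default 999).
#' @param seed optional integer seed.
#' @param method `"sample"` (default) or `"exhaustive"` — enumerate every
#'   equal-sized tip subset (small trees only).
#' @return Data frame with one row per metric (`NRI`, `NTI`): columns
#'   `metric`, `value`, `obs`, `null_mean`, `null_sd`, `n_null`, `flag`
#'   (`"ok"`, or `"degenerate_null"` when the null has zero spread, e.g. the
#'   set spans all tips — the value is then `NA`).
#' @export
nri_nti <- function(tree, species, n_shuffle = 999, seed = NULL,
                    method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  check_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  idx <- match_tips(tree, species)
  k <- length(idx)
  if (k < 2) stop("need at least two species")
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label]   # row order = tip order
  obs <- c(mpd = mpd_from_dist(D, idx), mntd = mntd_from_dist(D, idx))
  sets <- if (method == "exhaustive") {
    if (choose(n, k) > 2e4)
      stop("exhaustive enumeration infeasible: choose(", n, ", ", k, ") subsets")
    utils::combn(n, k, simplify = FALSE)
  } else {
    replicate(n_shuffle, sample.int(n, k), simplify = FALSE)
  }
  null_mpd <- vapply(sets, function(s) mpd_from_dist(D, s), numeric(1))
  null_mntd <- vapply(sets, function(s) mntd_from_dist(D, s), numeric(1))
  one <- function(metric, o, null) {
    s <- sd(null)
    if (!is.finite(s) || s == 0)
      return(data.frame(metric = metric, value = NA_real_, obs = o,
                        null_mean = mean(null), null_sd = s,
                        n_null = length(null), flag = "degenerate_null"))
    data.frame(metric = metric, value = -(o - mean(null)) / s, obs = o,
               null_mean = mean(null), null_sd = s, n_null = length(null),
               flag = "ok")
  }
  out <- rbind(one("NRI", obs["mpd"], null_mpd),
               one("NTI", obs["mntd"], null_mntd))
  rownames(out) <- NULL
  out
}
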