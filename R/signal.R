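## Resolve tip states: accepts a vector named by tip label (any order,
## possibly partial) or an unnamed vector in tip order. Tips without a
## state are dropped together with their induced subtree.
resolve_states <- function(tree, tip_states) {
  x <- as.character(tip_states)
  if (!is.null(names(tip_states))) {
    unknown <- setdiff(names(tip_states), tree$tip.label)
    if (length(unknown))
      stop("states given for unknown tips: ", paste(unknown, collapse = ", "))
    x <- x[match(tree$tip.label, names(tip_states))]
  } else if (length(x) != length(tree$tip.label)) {
    stop("unnamed `tip_states` must have one entry per tip")
  }
  keep <- !is.na(x)
  if (sum(keep) < 2) stop("fewer than two scored tips")
  if (!all(keep)) tree <- ape::keep.tip(tree, tree$tip.label[keep])
  list(tree = tree, states = x[keep])
}

unit_cost_matrix <- function(states) {
  C <- 1 - diag(length(states))
  dimnames(C) <- list(states, states)
  C
}

#' Sankoff parsimony score
#'
#' Exact minimal total substitution cost of a discrete trait on a rooted
#' tree under an arbitrary cost matrix, by the Sankoff dynamic program
#' (tips-to-root minimization over child-state transitions; polytomies are
#' handled natively). The default cost matrix charges 1 for every state
#' change, under which the score is the parsimony length.
#'
#' @param tree rooted `phylo` object (branch lengths ignored).
#' @param tip_states character/factor vector of states, named by tip label
#'   (or unnamed in tip order); `NA`-scored tips are dropped with their
#'   induced subtree.
#' @param cost square cost matrix with zero diagonal and non-negative
#'   entries, dimnames giving the states; default: unit costs over the
#'   observed states.
#' @return Minimal total cost (scalar; a non-negative integer under unit
#'   costs).
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' sankoff_score(tr, c(a = "x", b = "x", c = "y", d = "y"))  # 1
#' @export
sankoff_score <- function(tree, tip_states, cost = NULL) {
  rs <- resolve_states(tree, tip_states)
  tree <- rs$tree; x <- rs$states
  states <- if (is.null(cost)) sort(unique(x)) else rownames(cost)
  if (is.null(cost)) cost <- unit_cost_matrix(states)
  if (is.null(rownames(cost)) || !identical(rownames(cost), colnames(cost)))
    stop("`cost` must have identical row and column state names")
  if (any(diag(cost) != 0) || any(cost < 0))
    stop("`cost` must be non-negative with a zero diagonal")
  bad <- setdiff(unique(x), states)
  if (length(bad))
    stop("state(s) not in the cost matrix: ", paste(bad, collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  S <- length(states)
  M <- matrix(0, max(tree$edge), S)
  M[seq_len(n), ] <- Inf
  M[cbind(seq_len(n), match(x, states))] <- 0
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    trans <- vapply(seq_len(S), function(s) min(M[ch, ] + cost[s, ]),
                    numeric(1))
    M[p, ] <- M[p, ] + trans
  }
  min(M[n + 1L, ])
}

#' Permutation test for phylogenetic signal in a discrete trait
#'
#' Compares the observed Sankoff score with the scores of `n_perm` traits
#' obtained by randomly arraying the observed states across the tips.
#' `p = (1 + #\{permuted score <= observed\}) / (n_perm + 1)`: a low p-value
#' means the trait requires fewer changes than random arrangements, i.e.
#' phylogenetic signal.
#'
#' @inheritParams sankoff_score
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return List of class `sankoff_test`: `score`, `p`, `n_perm`, `null`
#'   (permuted scores), `flag` (`"ok"` or `"degenerate_trait"` for a
#'   single-state trait, where `p` is `NA`).
#' @export
sankoff_signal_test <- function(tree, tip_states, cost = NULL, n_perm = 999,
                                seed = NULL) {
  rs <- resolve_states(tree, tip_states)
  if (!is.null(seed)) set.seed(seed)
  if (length(rs$states) < 3) stop("need at least three scored tips")
  obs <- sankoff_score(rs$tree, setNames(rs$states, rs$tree$tip.label), cost)
  if (length(unique(rs$states)) < 2)
    return(structure(list(score = obs, p = NA_real_, n_perm = n_perm,
                          null = NULL, flag = "degenerate_trait"),
                     class = "sankoff_test"))
  null <- vapply(seq_len(n_perm), function(k)
    sankoff_score(rs$tree, setNames(sample(rs$states), rs$tree$tip.label),
                  cost), numeric(1))
  structure(list(score = obs, p = (1 + sum(null <= obs)) / (n_perm + 1),
                 n_perm = n_perm, null = null, flag = "ok"),
            class = "sankoff_test")
}

#' @export
print.sankoff_test <- function(x, ...) {
  cat("Sankoff parsimony signal test: score =", x$score)
  if (x$flag == "ok") cat(", p =", signif(x$p, 3),
                          paste0("(", x$n_perm, " permutations)\n"))
  else cat(" [", x$flag, "]\n")
  invisible(x)
}

## Sum of sister-clade differences in nodal values, vectorized over the
## columns of X (tips x m, tree tip order). Nodal values are means of
## daughter values, estimated tips-to-root; polytomies contribute the sum
## of absolute differences over consecutive daughter pairs.
d_sum_multi <- function(tree, X) {
  X <- as.matrix(X)
  n <- length(tree$tip.label)
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(ed[, 2], ed[, 1])
  node_order <- unique(ed[, 1])          # bottom-up
  V <- matrix(NA_real_, max(ed), ncol(X))
  V[seq_len(n), ] <- X
  d <- numeric(ncol(X))
  for (nd in node_order) {
    kids <- children[[as.character(nd)]]
    vals <- V[kids, , drop = FALSE]
    for (i in seq_len(length(kids) - 1L))
      d <- d + abs(vals[i, ] - vals[i + 1L, ])
    V[nd, ] <- colMeans(vals)
  }
  d
}

## Brownian-threshold binary traits: simulate Brownian motion along the
## tree and assign state 1 to the k tips with the largest values
## (rank threshold, so prevalence is exact by construction).
brownian_threshold_traits <- function(tree, k, n_sim) {
  B <- phytools::fastBM(tree, nsim = n_sim)
  if (is.null(dim(B))) B <- matrix(B, ncol = 1, dimnames = list(names(B)))
  B <- B[tree$tip.label, , drop = FALSE]
  X <- apply(B, 2, function(b) as.numeric(rank(-b, ties.method = "first") <= k))
  matrix(X, nrow = length(tree$tip.label))
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Measures phylogenetic signal in a binary trait by scaling the observed
#' sum of sister-clade differences in nodal values (`d_obs`, nodal values
#' estimated by averaging daughter values from the tips to the root)
#' between two simulated expectations:
#' `D = (d_obs - mean(d_Brownian)) / (mean(d_random) - mean(d_Brownian))`,
#' where the random null permutes tip states (preserving prevalence) and
#' the Brownian null thresholds continuous Brownian-motion traits at the
#' observed prevalence. D is 1 for a phylogenetically random trait, 0 for a
#' trait produced by thresholding Brownian evolution, below 0 for traits
#' more conserved than the Brownian expectation and above 1 for traits more
#' labile than random.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tip_states binary trait (two levels), named by tip label or
#'   unnamed in tip order; `NA` tips are dropped.
#' @param n_perm permutations/simulations per null (default 1000).
#' @param seed optional integer seed.
#' @return List of class `fp_d`: `d`, `p_random` (fraction of random-null d
#'   values at or below `d_obs`; small = more conserved than random),
#'   `p_brownian` (fraction of Brownian-null d values at or above `d_obs`;
#'   small = more labile than Brownian), `d_obs`, `mean_random`,
#'   `mean_brownian`, `n_perm`, `k` (count of the rarer state), `n_tips`,
#'   `flag` (`"ok"`, `"degenerate_trait"`, or `"null_means_coincide"`; `d`
#'   is `NA` unless `"ok"`).
#' @export
fritz_purvis_d <- function(tree, tip_states, n_perm = 1000, seed = NULL) {
  rs <- resolve_states(tree, tip_states)
  tree <- rs$tree
  check_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  lev <- sort(unique(rs$states))
  if (length(lev) > 2) stop("trait has more than two states")
  blank <- list(d = NA_real_, p_random = NA_real_, p_brownian = NA_real_,
                d_obs = NA_real_, mean_random = NA_real_,
                mean_brownian = NA_real_, n_perm = n_perm,
                k = NA_integer_, n_tips = length(tree$tip.label))
  if (length(lev) < 2)
    return(structure(c(blank, flag = "degenerate_trait"), class = "fp_d"))
  x <- as.numeric(rs$states == lev[2])
  k <- min(sum(x), sum(1 - x))           # rarer-state count
  d_obs <- d_sum_multi(tree, matrix(x, ncol = 1))
  Xr <- vapply(seq_len(n_perm), function(i) sample(x), numeric(length(x)))
  d_rand <- d_sum_multi(tree, Xr)
  Xb <- brownian_threshold_traits(tree, sum(x), n_perm)
  d_brw <- d_sum_multi(tree, Xb)
  mr <- mean(d_rand); mb <- mean(d_brw)
  if (!is.finite(mr - mb) || mr == mb) {
    blank[c("d_obs", "mean_random", "mean_brownian", "k")] <-
      list(d_obs, mr, mb, k)
    return(structure(c(blank, flag = "null_means_coincide"), class = "fp_d"))
  }
  structure(list(d = (d_obs - mb) / (mr - mb),
                 p_random = mean(d_rand <= d_obs),
                 p_brownian = mean(d_brw >= d_obs),
                 d_obs = d_obs, mean_random = mr, mean_brownian = mb,
                 n_perm = n_perm, k = k, n_tips = length(tree$tip.label),
                 flag = "ok"),
            class = "fp_d")
}

#' @export
print.fp_d <- function(x, ...) {
  if (x$flag != "ok") {
    cat("Fritz-Purvis D: undefined [", x$flag, "]\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("Fritz-Purvis D = %.3f (d_obs %.3f; random mean %.3f,",
                     " Brownian mean %.3f; %d tips, rarer state n = %d)\n"),
              x$d, x$d_obs, x$mean_random, x$mean_brownian, x$n_tips, x$k))
  cat(sprintf("  p(random null d <= d_obs) = %.3f, p(Brownian null d >= d_obs) = %.3f, %d permutations\n",
              x$p_random, x$p_brownian, x$n_perm))
  invisible(x)
}
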