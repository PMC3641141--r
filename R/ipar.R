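## Incidence-matrix PD engine: A[tip, edge] = 1 when the edge lies on the
## tip's root path. For a 0/1 membership matrix U (rows = neighborhoods,
## cols = tips in tree tip order), E = U %*% A counts, per edge, the members
## descending through it; rooted PD is the length of edges with E > 0, and
## the unrooted variant subtracts edges shared by every member (E == set
## size), which zeroes singletons as required.
pd_incidence <- function(tree) {
  paths <- root_paths(tree)
  n <- length(tree$tip.label)
  A <- matrix(0, n, nrow(tree$edge))
  for (i in seq_len(n)) A[i, paths[[i]]] <- 1
  list(A = A, el = tree$edge.length, labels = tree$tip.label)
}

pd_of_membership <- function(U, inc, rooted = TRUE) {
  E <- U %*% inc$A
  out <- as.numeric((E > 0) %*% inc$el)
  if (!rooted) {
    size <- rowSums(U)
    out <- out - as.numeric((E >= pmax(size, 1)) %*% inc$el)
    out[size == 0] <- 0
  }
  out
}

## Per-focal neighborhood membership matrices, one per radius, with columns
## in tree tip order. mind: focals x neighbor-species min-distance matrix.
membership_by_radius <- function(mind, lev, tree_labels, radii) {
  col <- match(lev, tree_labels)
  lapply(radii, function(r) {
    M <- matrix(0, nrow(mind), length(tree_labels))
    M[, col] <- (mind <= r) + 0
    M
  })
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

prune_to_plot <- function(tree, plot_species) {
  miss <- setdiff(plot_species, tree$tip.label)
  if (length(miss))
    stop("species not on the phylogeny: ", paste(miss, collapse = ", "))
  extra <- setdiff(tree$tip.label, plot_species)
  if (length(extra)) {
    message("pruning ", length(extra),
            " tip(s) not present in the plot from the phylogeny")
    tree <- ape::keep.tip(tree, plot_species)
  }
  tree
}

#' Observed individual phylogenetic-area relationship
#'
#' For one focal species, the mean Faith's PD of the neighborhood species
#' set around its edge-buffered individuals, per radius. Neighborhoods
#' follow the richness convention (focal species excluded by default);
#' empty neighborhoods contribute PD 0, singletons their root path length
#' under the rooted convention — both counted in the output because they
#' dilute the average at small radii.
#'
#' @inheritParams isar_curve
#' @param tree rooted `phylo` with branch lengths whose tips cover the
#'   plot's species (extra tips are pruned).
#' @param radii neighborhood radii in meters (default [ipar_radii()]).
#' @param rooted PD convention, see [faith_pd].
#' @return Data frame: `species`, `radius_m`, `n_focals`, `obs_pd`,
#'   `n_empty`, `n_singleton`.
#' @export
ipar_observed <- function(plot, tree, species, radii = ipar_radii(),
                          buffer = 50, exclude_focal_species = TRUE,
                          rooted = TRUE) {
  radii <- check_radii(radii)
  tree <- prune_to_plot(tree, sort(unique(plot$stems$species)))
  check_phylogeny(tree)
  foc <- eligible_focals(plot, species, buffer)
  if (nrow(foc) == 0L)
    stop("species `", species, "` has no individual >= ", buffer,
         " m from the plot edge")
  nb <- neighbor_stems(plot, species, exclude_focal_species)
  lev <- sort(unique(nb$species))
  skip <- if (exclude_focal_species) NULL else match(foc$stem_id, nb$stem_id)
  mind <- species_min_dist(foc[c("x", "y")], nb, lev, skip)
  inc <- pd_incidence(tree)
  Ms <- membership_by_radius(mind, lev, tree$tip.label, radii)
  pd <- vapply(Ms, function(M) pd_of_membership(M, inc, rooted),
               numeric(nrow(foc)))
  if (!is.matrix(pd)) pd <- matrix(pd, nrow = nrow(foc))
  size <- vapply(Ms, rowSums, numeric(nrow(foc)))
  if (!is.matrix(size)) size <- matrix(size, nrow = nrow(foc))
  data.frame(species = species, radius_m = radii, n_focals = nrow(foc),
             obs_pd = colMeans(pd),
             n_empty = colSums(size == 0), n_singleton = colSums(size == 1))
}

#' Standardized effect size of neighborhood PD for one species
#'
#' The IPAR null model: species names are shuffled across the tips of the
#' plot phylogeny (topology, branch lengths and all neighborhood
#' compositions held fixed), the mean neighborhood PD curve is recomputed
#' under each shuffle, and
#' `ses = (obs_pd - mean(null_pd)) / sd(null_pd)` per radius, so positive
#' values mean the average individual carries more phylogenetic diversity in
#' its neighborhood than expected given the observed richness. Status is the
#' two-sided Monte-Carlo rank designation at level `alpha` (phylogenetic
#' accumulator / neutral / repeller).
#'
#' @inheritParams ipar_observed
#' @param n_shuffle number of tip shuffles (default 999, minimum 99 for the
#'   sampled null).
#' @param alpha two-sided level for the status call (default 0.05).
#' @param standardize `"after"` (default: average PD over focals, then
#'   standardize the curve) or `"per_focal"` (standardize each focal's PD
#'   against its own null, then average the per-focal scores; the status
#'   call is always curve-level).
#' @param method `"sample"` or `"exhaustive"` (all tip permutations; trees
#'   of at most 7 tips).
#' @param seed optional integer seed.
#' @return Data frame: `species`, `radius_m`, `n_focals`, `obs_pd`,
#'   `null_mean`, `null_sd`, `ses_pd`, `status` (factor accumulator /
#'   neutral / repeller), `n_empty`, `n_singleton`, `flag` (`"ok"` or
#'   `"degenerate_null"` where the null has zero spread, e.g. neighborhoods
#'   that always contain every species; `ses_pd` is then `NA` and the
#'   status neutral).
#' @export
ses_pd <- function(plot, tree, species, radii = ipar_radii(), buffer = 50,
                   n_shuffle = 999, alpha = 0.05,
                   exclude_focal_species = TRUE, rooted = TRUE,
                   standardize = c("after", "per_focal"),
                   method = c("sample", "exhaustive"), seed = NULL) {
  standardize <- match.arg(standardize)
  method <- match.arg(method)
  radii <- check_radii(radii)
  if (method == "sample" && n_shuffle < 99)
    stop("n_shuffle must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  tree <- prune_to_plot(tree, sort(unique(plot$stems$species)))
  check_phylogeny(tree)
  obs <- ipar_observed(plot, tree, species, radii, buffer,
                       exclude_focal_species, rooted)
  foc <- eligible_focals(plot, species, buffer)
  nb <- neighbor_stems(plot, species, exclude_focal_species)
  lev <- sort(unique(nb$species))
  skip <- if (exclude_focal_species) NULL else match(foc$stem_id, nb$stem_id)
  mind <- species_min_dist(foc[c("x", "y")], nb, lev, skip)
  inc <- pd_incidence(tree)
  Ms <- membership_by_radius(mind, lev, tree$tip.label, radii)
  P0 <- vapply(Ms, function(M) pd_of_membership(M, inc, rooted),
               numeric(nrow(foc)))
  if (!is.matrix(P0)) P0 <- matrix(P0, nrow = nrow(foc))
  n_tip <- length(tree$tip.label)
  perms <- if (method == "exhaustive") {
    if (n_tip > 7) stop("exhaustive permutations infeasible beyond 7 tips")
    all_permutations(n_tip)
  } else {
    replicate(n_shuffle, sample.int(n_tip), simplify = FALSE)
  }
  m <- length(perms)
  ens <- matrix(NA_real_, m, length(radii))
  fsum <- fss <- matrix(0, nrow(foc), length(radii))
  for (k in seq_len(m)) {
    invp <- order(perms[[k]])   # U[, v] = M[, pi^-1(v)]
    Pk <- vapply(Ms, function(M) pd_of_membership(M[, invp, drop = FALSE],
                                                  inc, rooted),
                 numeric(nrow(foc)))
    if (!is.matrix(Pk)) Pk <- matrix(Pk, nrow = nrow(foc))
    ens[k, ] <- colMeans(Pk)
    if (standardize == "per_focal") { fsum <- fsum + Pk; fss <- fss + Pk^2 }
  }
  attr(ens, "radii") <- radii
  cls <- classify_status(obs$obs_pd, ens, alpha)
  null_mean <- colMeans(ens)
  null_sd <- apply(ens, 2, sd)
  ses <- if (standardize == "after") {
    ifelse(null_sd > 0, (obs$obs_pd - null_mean) / null_sd, NA_real_)
  } else {
    mu <- fsum / m
    s2 <- pmax(0, (fss - m * mu^2) / (m - 1))
    z <- (P0 - mu) / sqrt(s2)
    z[!is.finite(z)] <- NA
    colMeans(z, na.rm = TRUE)
  }
  flag <- ifelse(null_sd > 0, "ok", "degenerate_null")
  status <- cls$status
  status[flag != "ok"] <- "neutral"
  data.frame(species = species, radius_m = radii, n_focals = obs$n_focals,
             obs_pd = obs$obs_pd, null_mean = null_mean, null_sd = null_sd,
             ses_pd = ses, status = status,
             n_empty = obs$n_empty, n_singleton = obs$n_singleton,
             flag = flag)
}

#' Individual phylogenetic-area relationships for a plot
#'
#' Runs [ses_pd] for every focal species with at least one edge-buffered
#' individual and binds the per-species tables; species without eligible
#' focals are skipped and listed in the `"skipped"` attribute.
#'
#' @inheritParams ses_pd
#' @param species character vector of focal species (default: all).
#' @return Tidy data frame as in [ses_pd], one block per species.
#' @export
ipar <- function(plot, tree, species = NULL, radii = ipar_radii(),
                 buffer = 50, n_shuffle = 999, alpha = 0.05,
                 exclude_focal_species = TRUE, rooted = TRUE,
                 standardize = c("after", "per_focal"), seed = NULL) {
  stopifnot(inherits(plot, "census_plot"))
  standardize <- match.arg(standardize)
  if (!is.null(seed)) set.seed(seed)
  tree <- prune_to_plot(tree, sort(unique(plot$stems$species)))
  if (is.null(species)) species <- sort(unique(plot$stems$species))
  rows <- list(); skipped <- list()
  for (sp in species) {
    foc <- eligible_focals(plot, sp, buffer)
    if (nrow(foc) == 0L) {
      message("skipping `", sp, "`: no individual >= ", buffer,
              " m from the plot edge")
      skipped[[sp]] <- data.frame(species = sp, reason = "no eligible focal")
      next
    }
    rows[[sp]] <- ses_pd(plot, tree, sp, radii, buffer, n_shuffle, alpha,
                         exclude_focal_species, rooted, standardize)
  }
  if (!length(rows))
    stop("no species had an eligible focal individual at buffer = ", buffer)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(species = character(), reason = character())
  out
}
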