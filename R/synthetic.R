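species_names <- function(n) sprintf("sp%03d", seq_len(n))

## Log-series abundance sampler: P(k) proportional to x^k / k, k >= 1.
rlogseries <- function(n, x) {
  stopifnot(x > 0, x < 1)
  kmax <- max(1000, ceiling(10 / (1 - x)))
  k <- seq_len(kmax)
  p <- x^k / k
  sample(k, n, replace = TRUE, prob = p)
}

#' Specify a synthetic mapped forest
#'
#' Describes a multispecies mapped point pattern with known ground truth:
#' per-species abundances (uniform or log-series, the latter mimicking
#' tropical rank-abundance shape), and per-species placement processes —
#' complete spatial randomness, Thomas cluster processes, or engineered
#' `attract`/`repel` species whose density is multiplied (or divided)
#' inside discs of a given effect radius around a target species' stems,
#' yielding ground-truth accumulators and repellers at radii up to the
#' effect radius.
#'
#' @param window `c(xmin, ymin, xmax, ymax)` in meters (default 200 x 200).
#' @param n_species number of species.
#' @param abundance `"logseries"` (default) or `"uniform"`.
#' @param stems_per_species per-species count under `"uniform"` abundance.
#' @param logseries_x log-series parameter in (0, 1) (default 0.99, mean
#'   abundance about 22).
#' @param placements named list (names = species such as `"sp001"`), each
#'   element one of
#'   `list(type = "thomas", kappa = , mu = , sigma = )` (parent intensity
#'   per m^2, mean offspring per parent — used only for the parent count —
#'   and Gaussian dispersal sd in meters),
#'   `list(type = "attract", target = , radius = , multiplier = )`, or
#'   `list(type = "repel", target = , radius = , multiplier = )`.
#'   Unlisted species are placed uniformly at random. `attract` multiplies
#'   the placement density by `multiplier` (> 1) inside discs of `radius`
#'   meters around the target species' stems; `repel` divides it.
#' @param seed integer seed stored in the spec; [generate_forest] seeds from
#'   it so a spec maps to one plot.
#' @return List of class `forest_spec`.
#' @export
forest_spec <- function(window = c(0, 0, 200, 200), n_species = 20,
                        abundance = c("logseries", "uniform"),
                        stems_per_species = 100, logseries_x = 0.99,
                        placements = list(), seed = 1) {
  abundance <- match.arg(abundance)
  window <- as.numeric(window)
  names(window) <- c("xmin", "ymin", "xmax", "ymax")
  stopifnot(n_species >= 2, stems_per_species >= 1,
            logseries_x > 0, logseries_x < 1)
  half <- min(window["xmax"] - window["xmin"],
              window["ymax"] - window["ymin"]) / 2
  nm <- species_names(n_species)
  for (sp in names(placements)) {
    pl <- placements[[sp]]
    if (!sp %in% nm) stop("placement for unknown species `", sp, "`")
    if (!pl$type %in% c("thomas", "attract", "repel"))
      stop("unknown placement type `", pl$type, "`")
    if (pl$type == "thomas" &&
        (pl$kappa <= 0 || pl$mu <= 0 || pl$sigma <= 0))
      stop("thomas parameters must be positive")
    if (pl$type %in% c("attract", "repel")) {
      if (pl$radius <= 0 || pl$radius >= half)
        stop("effect radius must be positive and below the window half-width")
      if (pl$multiplier <= 1)
        stop("attract/repel multiplier must exceed 1")
      if (!pl$target %in% nm || identical(pl$target, sp))
        stop("attract/repel target must be another species of the plot")
      tp <- placements[[pl$target]]
      if (!is.null(tp) && tp$type %in% c("attract", "repel"))
        stop("attract/repel targets must themselves be random or thomas species")
    }
  }
  structure(list(window = window, n_species = n_species,
                 abundance = abundance,
                 stems_per_species = stems_per_species,
                 logseries_x = logseries_x, placements = placements,
                 seed = as.integer(seed)),
            class = "forest_spec")
}

runif_window <- function(n, w) {
  data.frame(x = runif(n, w["xmin"], w["xmax"]),
             y = runif(n, w["ymin"], w["ymax"]))
}

place_thomas <- function(n, w, kappa, mu, sigma) {
  area <- (w["xmax"] - w["xmin"]) * (w["ymax"] - w["ymin"])
  n_par <- max(1L, stats::rpois(1, kappa * area))
  par <- runif_window(n_par, w)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    need <- n - got
    pid <- sample.int(n_par, need, replace = TRUE)
    x <- par$x[pid] + rnorm(need, 0, sigma)
    y <- par$y[pid] + rnorm(need, 0, sigma)
    ok <- x >= w["xmin"] & x <= w["xmax"] & y >= w["ymin"] & y <= w["ymax"]
    keep <- min(sum(ok), need)
    if (keep) {
      out[got + seq_len(keep), ] <- cbind(x[ok], y[ok])[seq_len(keep), ]
      got <- got + keep
    }
  }
  data.frame(x = out[, 1], y = out[, 2])
}

place_modulated <- function(n, w, target_xy, radius, multiplier, mode) {
  r2 <- radius^2
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    prop <- runif_window(2L * (n - got) + 8L, w)
    near <- vapply(seq_len(nrow(prop)), function(i)
      any((target_xy$x - prop$x[i])^2 + (target_xy$y - prop$y[i])^2 <= r2),
      logical(1))
    dens <- if (mode == "attract") ifelse(near, multiplier, 1)
            else ifelse(near, 1 / multiplier, 1)
    acc <- runif(nrow(prop)) <= dens / (if (mode == "attract") multiplier else 1)
    keep <- which(acc)
    keep <- keep[seq_len(min(length(keep), n - got))]
    if (length(keep)) {
      out[got + seq_along(keep), ] <- cbind(prop$x[keep], prop$y[keep])
      got <- got + length(keep)
    }
  }
  data.frame(x = out[, 1], y = out[, 2])
}

#' Generate a synthetic mapped forest
#'
#' Realizes a [forest_spec] as a [census_plot]: abundances are drawn from
#' the spec's abundance model, positions from the per-species placement
#' processes (all conditioned on their counts, so replicate plots differ
#' only in locations), and dbh values from `1 + Lognormal(log 2, 0.8)` cm.
#' Deterministic given the spec's seed.
#'
#' @param spec a [forest_spec].
#' @return A [census_plot]; attribute `"truth"` is a data frame with one
#'   row per species recording its placement process and (for
#'   `attract`/`repel`) the target, effect radius and multiplier.
#' @export
generate_forest <- function(spec) {
  stopifnot(inherits(spec, "forest_spec"))
  set.seed(spec$seed)
  w <- spec$window
  nm <- species_names(spec$n_species)
  counts <- switch(spec$abundance,
    uniform = rep(spec$stems_per_species, spec$n_species),
    logseries = rlogseries(spec$n_species, spec$logseries_x))
  names(counts) <- nm
  get_type <- function(sp) {
    pl <- spec$placements[[sp]]
    if (is.null(pl)) "random" else pl$type
  }
  types <- vapply(nm, get_type, character(1))
  pos <- setNames(vector("list", spec$n_species), nm)
  for (sp in nm[types %in% c("random", "thomas")]) {
    pl <- spec$placements[[sp]]
    pos[[sp]] <- if (types[sp] == "random") runif_window(counts[sp], w)
      else place_thomas(counts[sp], w, pl$kappa, pl$mu, pl$sigma)
  }
  for (sp in nm[types %in% c("attract", "repel")]) {
    pl <- spec$placements[[sp]]
    pos[[sp]] <- place_modulated(counts[sp], w, pos[[pl$target]],
                                 pl$radius, pl$multiplier, pl$type)
  }
  stems <- do.call(rbind, lapply(nm, function(sp)
    data.frame(stem_id = sprintf("%s_%04d", sp, seq_len(counts[sp])),
               species = sp, x = pos[[sp]]$x, y = pos[[sp]]$y)))
  stems$dbh <- 1 + stats::rlnorm(nrow(stems), log(2), 0.8)
  out <- census_plot(stems, w)
  truth <- data.frame(
    species = nm, n = as.integer(counts), placement = unname(types),
    target = vapply(nm, function(sp) {
      pl <- spec$placements[[sp]]
      if (is.null(pl$target)) NA_character_ else pl$target
    }, character(1)),
    radius = vapply(nm, function(sp) {
      pl <- spec$placements[[sp]]
      if (is.null(pl$radius)) NA_real_ else pl$radius
    }, numeric(1)),
    multiplier = vapply(nm, function(sp) {
      pl <- spec$placements[[sp]]
      if (is.null(pl$multiplier)) NA_real_ else pl$multiplier
    }, numeric(1)))
  rownames(truth) <- NULL
  attr(out, "truth") <- truth
  attr(out, "spec") <- spec
  out
}

#' Simulate a calibrated phylogeny with a tip trait
#'
#' Pure-birth (Yule) tree with exactly `n_tips` tips via [ape::rphylo]
#' (ultrametric, branch lengths in time units), plus an optional binary tip
#' trait with exact prevalence `round(prevalence * n_tips)`: `"shuffle"`
#' assigns state 1 to a uniformly random tip subset (no phylogenetic
#' signal), `"brownian_threshold"` thresholds a Brownian-motion trait at the
#' rank giving that prevalence (signal inherited from the tree).
#'
#' @param n_tips number of tips (>= 4).
#' @param birth Yule speciation rate (default 1; time-rescales the tree).
#' @param trait `"none"`, `"shuffle"`, or `"brownian_threshold"`.
#' @param prevalence fraction of tips in state 1, in (0, 1) (default 0.5).
#' @param tip_labels optional character vector of tip names (default
#'   `sp001`... to match [generate_forest]).
#' @param seed optional integer seed.
#' @return List with elements `tree` (a `phylo`) and `trait` (named 0/1
#'   vector, or `NULL` for `trait = "none"`).
#' @export
generate_tree <- function(n_tips, birth = 1,
                          trait = c("none", "shuffle", "brownian_threshold"),
                          prevalence = 0.5, tip_labels = NULL, seed = NULL) {
  trait <- match.arg(trait)
  stopifnot(n_tips >= 4, birth > 0, prevalence > 0, prevalence < 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  tree$tip.label <- if (is.null(tip_labels)) species_names(n_tips) else {
    stopifnot(length(tip_labels) == n_tips)
    as.character(tip_labels)
  }
  tr <- NULL
  if (trait != "none") {
    k <- round(prevalence * n_tips)
    if (k == 0 || k == n_tips) stop("prevalence leaves a constant trait")
    tr <- if (trait == "shuffle") {
      x <- numeric(n_tips); x[sample.int(n_tips, k)] <- 1; x
    } else {
      as.numeric(brownian_threshold_traits(tree, k, 1))
    }
    names(tr) <- tree$tip.label
  }
  list(tree = tree, trait = tr)
}
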