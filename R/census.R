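#' Construct a mapped census plot
#'
#' A `census_plot` bundles a rectangular observation window with the mapped,
#' identified stems inside it: one row per individual with a species identity,
#' x/y coordinates in meters and a diameter at breast height (dbh) in cm.
#'
#' @param stems data frame with columns `stem_id`, `species`, `x`, `y`, `dbh`.
#' @param window numeric vector `c(xmin, ymin, xmax, ymax)` in meters.
#' @return An object of class `census_plot`: a list with elements `window`
#'   (named numeric of length 4) and `stems` (validated data frame).
#' @examples
#' stems <- data.frame(stem_id = 1:3, species = c("a", "a", "b"),
#'                     x = c(10, 20, 30), y = c(10, 20, 30), dbh = c(1, 2, 3))
#' census_plot(stems, window = c(0, 0, 100, 100))
#' @export
census_plot <- function(stems, window) {
  window <- as.numeric(window)
  if (length(window) != 4 || anyNA(window))
    stop("`window` must be c(xmin, ymin, xmax, ymax)")
  names(window) <- c("xmin", "ymin", "xmax", "ymax")
  if (window["xmax"] <= window["xmin"] || window["ymax"] <= window["ymin"])
    stop("degenerate window: xmax > xmin and ymax > ymin required")
  stems <- as.data.frame(stems)
  need <- c("stem_id", "species", "x", "y", "dbh")
  miss <- setdiff(need, names(stems))
  if (length(miss))
    stop("stems table lacks column(s): ", paste(miss, collapse = ", "))
  stems <- stems[need]
  stems$species <- as.character(stems$species)
  stems$stem_id <- as.character(stems$stem_id)
  for (v in c("x", "y", "dbh")) {
    stems[[v]] <- as.numeric(stems[[v]])
    if (!all(is.finite(stems[[v]])))
      stop("non-finite values in column `", v, "`")
  }
  if (nrow(stems) == 0L) stop("empty census: no stems")
  if (any(stems$dbh <= 0)) stop("dbh must be > 0 cm for every stem")
  if (anyDuplicated(stems$stem_id))
    stop("duplicate stem_id: ",
         paste(unique(stems$stem_id[duplicated(stems$stem_id)])[1:3],
               collapse = ", "))
  out <- stems$x < window["xmin"] | stems$x > window["xmax"] |
         stems$y < window["ymin"] | stems$y > window["ymax"]
  if (any(out))
    stop(sum(out), " stem(s) fall outside the window (first: stem_id ",
         stems$stem_id[which(out)[1]], ")")
  rownames(stems) <- NULL
  structure(list(window = window, stems = stems), class = "census_plot")
}

#' @export
print.census_plot <- function(x, ...) {
  w <- x$window
  cat(sprintf("Mapped census plot: %g x %g m window, %d stems, %d species\n",
              w["xmax"] - w["xmin"], w["ymax"] - w["ymin"],
              nrow(x$stems), length(unique(x$stems$species))))
  invisible(x)
}

#' @export
summary.census_plot <- function(object, ...) {
  print(object)
  ab <- sort(table(object$stems$species), decreasing = TRUE)
  cat("dbh range [cm]:", paste(signif(range(object$stems$dbh), 4), collapse = " - "),
      "\nabundance: median", median(ab), ", max", max(ab),
      "(", names(ab)[1], ")\n")
  invisible(ab)
}

#' Neighborhood radius grids
#'
#' Default sets of neighborhood radii (meters): `isar_radii()` returns the
#' 1-50 m grid in 1 m increments used for species richness neighborhoods;
#' `ipar_radii()` returns the sparser 1-10, 15, 20, 30, 40, 50 m grid used
#' for phylogenetic diversity neighborhoods.
#'
#' @return Strictly increasing numeric vector of radii in meters.
#' @export
isar_radii <- function() 1:50

#' @rdname isar_radii
#' @export
ipar_radii <- function() c(1:10, 15, 20, 30, 40, 50)

check_radii <- function(radii) {
  radii <- as.numeric(radii)
  if (!length(radii) || any(!is.finite(radii)) || any(radii <= 0) ||
      is.unsorted(radii, strictly = TRUE))
    stop("`radii` must be a strictly increasing vector of positive distances")
  radii
}

#' Restrict a plot by dbh and abundance
#'
#' Applies the standard census filters before analysis: keep stems with
#' `dbh >= dbh_min` (cm), then keep species with at least `abundance_min`
#' surviving individuals. Species and stems removed are recorded in the
#' `"dropped"` attribute so filtered and unfiltered analyses can be
#' reconciled.
#'
#' @param plot a [census_plot].
#' @param dbh_min minimum dbh in cm (commonly 1 or 10).
#' @param abundance_min minimum number of individuals per species (commonly
#'   0 or 70).
#' @return A filtered [census_plot]; attribute `"dropped"` is a data frame
#'   with columns `species`, `reason`.
#' @export
apply_filters <- function(plot, dbh_min = 1, abundance_min = 0) {
  stopifnot(inherits(plot, "census_plot"), dbh_min >= 0, abundance_min >= 0)
  st <- plot$stems
  pre <- unique(st$species)
  st <- st[st$dbh >= dbh_min, , drop = FALSE]
  gone_dbh <- setdiff(pre, unique(st$species))
  ab <- table(st$species)
  keep <- names(ab)[ab >= abundance_min]
  gone_ab <- setdiff(unique(st$species), keep)
  st <- st[st$species %in% keep, , drop = FALSE]
  if (nrow(st) == 0L)
    stop("filters removed every stem (dbh_min = ", dbh_min,
         ", abundance_min = ", abundance_min, ")")
  out <- census_plot(st, plot$window)
  dropped <- rbind(
    if (length(gone_dbh)) data.frame(species = gone_dbh, reason = "below dbh_min"),
    if (length(gone_ab)) data.frame(species = gone_ab, reason = "below abundance_min"))
  attr(out, "dropped") <- if (is.null(dropped))
    data.frame(species = character(), reason = character()) else dropped
  out
}

edge_distance <- function(x, y, window) {
  pmin(x - window["xmin"], window["xmax"] - x,
       y - window["ymin"], window["ymax"] - y)
}

#' Focal individuals away from the plot edge
#'
#' Returns the stems of a focal species whose distance to every window edge
#' is at least `buffer` meters; only these individuals are used as
#' neighborhood centers, so that no neighborhood disc of radius up to
#' `buffer` spills outside the plot.
#'
#' @inheritParams apply_filters
#' @param species a species identity present in the plot.
#' @param buffer edge buffer in meters (boundary inclusive).
#' @return Data frame of focal stems (possibly zero rows when all stems sit
#'   within `buffer` of an edge).
#' @export
eligible_focals <- function(plot, species, buffer = 50) {
  stopifnot(inherits(plot, "census_plot"), buffer >= 0,
            is.character(species) || is.factor(species), length(species) == 1L)
  st <- plot$stems
  mine <- st[st$species == as.character(species), , drop = FALSE]
  if (nrow(mine) == 0L)
    stop("species `", species, "` is absent from the plot")
  keep <- edge_distance(mine$x, mine$y, plot$window) >= buffer
  out <- mine[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Minimum distance from each focal to the nearest stem of every species.
## Wraps the compiled kernel; neighbor stems and focal self-exclusion are
## resolved here so callers only think in species terms.
species_min_dist <- function(focal_xy, stems, species_levels,
                             skip_stem = NULL) {
  sp <- match(stems$species, species_levels)
  skip <- if (is.null(skip_stem)) integer(nrow(focal_xy)) else
    as.integer(skip_stem)
  m <- min_dist_by_species(focal_xy$x, focal_xy$y, stems$x, stems$y,
                           as.integer(sp), length(species_levels), skip)
  colnames(m) <- species_levels
  m
}

neighbor_stems <- function(plot, species, exclude_focal_species = TRUE) {
  st <- plot$stems
  if (exclude_focal_species) st[st$species != species, , drop = FALSE] else st
}

#' Species in the neighborhood of a focal stem
#'
#' The set of species identities with at least one stem within Euclidean
#' distance `r` (disc membership closed: ties at exactly `r` included) of a
#' focal stem. By default the focal species itself is excluded, so richness
#' counts heterospecific species only; the focal stem is never its own
#' neighbor.
#'
#' @inheritParams eligible_focals
#' @param focal a single-row data frame identifying a stem of the plot (as
#'   returned by [eligible_focals]), or a `stem_id`.
#' @param r neighborhood radius in meters.
#' @param exclude_focal_species logical; drop conspecifics from the
#'   neighborhood (default TRUE).
#' @return Character vector of species identities (possibly empty).
#' @export
neighborhood_species <- function(plot, focal, r, exclude_focal_species = TRUE) {
  stopifnot(inherits(plot, "census_plot"), r > 0)
  st <- plot$stems
  if (is.data.frame(focal)) focal <- focal$stem_id
  i <- match(as.character(focal), st$stem_id)
  if (length(i) != 1L || is.na(i)) stop("`focal` does not identify a stem of the plot")
  sp <- st$species[i]
  nb <- neighbor_stems(plot, sp, exclude_focal_species)
  lev <- sort(unique(nb$species))
  if (!length(lev)) return(character())
  skip <- if (exclude_focal_species) NULL else match(st$stem_id[i], nb$stem_id)
  m <- species_min_dist(st[i, c("x", "y")], nb, lev,
                        skip_stem = if (is.null(skip)) NULL else skip)
  lev[m[1, ] <= r]
}

## Per-focal richness curve engine: n_focal x n_radii matrix of counts of
## species whose nearest stem lies within each radius.
richness_counts <- function(focal_xy, nb, species_levels, radii,
                            skip_stem = NULL) {
  if (!nrow(nb) || !length(species_levels))
    return(matrix(0L, nrow(focal_xy), length(radii)))
  m <- species_min_dist(focal_xy, nb, species_levels, skip_stem)
  cnt <- vapply(radii, function(r) rowSums(m <= r), numeric(nrow(focal_xy)))
  if (!is.matrix(cnt)) cnt <- matrix(cnt, nrow = nrow(focal_xy))
  cnt
}

#' Observed individual species-area relationship
#'
#' For one focal species, the mean number of (by default heterospecific)
#' species found within nested circular neighborhoods around its
#' edge-buffered individuals: the individual species-area relationship
#' (ISAR) curve.
#'
#' @inheritParams eligible_focals
#' @param radii neighborhood radii in meters, strictly increasing
#'   (default [isar_radii()]).
#' @param exclude_focal_species logical; count heterospecific species only
#'   (default TRUE).
#' @return Data frame with columns `species`, `radius_m`, `n_focals`,
#'   `obs_mean_richness`. Errors if the species has no eligible focal.
#' @export
isar_curve <- function(plot, species, radii = isar_radii(), buffer = 50,
                       exclude_focal_species = TRUE) {
  radii <- check_radii(radii)
  foc <- eligible_focals(plot, species, buffer)
  if (nrow(foc) == 0L)
    stop("species `", species, "` has no individual >= ", buffer,
         " m from the plot edge")
  nb <- neighbor_stems(plot, species, exclude_focal_species)
  lev <- sort(unique(nb$species))
  skip <- if (exclude_focal_species) NULL else match(foc$stem_id, nb$stem_id)
  cnt <- richness_counts(foc[c("x", "y")], nb, lev, radii, skip)
  data.frame(species = species, radius_m = radii, n_focals = nrow(foc),
             obs_mean_richness = colMeans(cnt))
}
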