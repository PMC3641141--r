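#' Heterogeneous Poisson null ensemble for one species
#'
#' Builds the null distribution of a species' ISAR curve: only the target
#' species' stems are relocated, in each of `n_sim` iterations, according to
#' an Epanechnikov-kernel intensity (default 50 m bandwidth) fitted to that
#' species' own observed pattern; every other species is kept fixed. Each
#' iteration preserves the target's stem count, recomputes the eligible
#' focals with the same edge buffer, and records the mean richness curve.
#'
#' Relocation erases the target's spatial structure below the bandwidth while
#' retaining its broad-scale (first-order, e.g. habitat-driven) distribution,
#' so departures of the observed curve from this ensemble reflect fine-scale
#' association with other species, not habitat preference.
#'
#' @inheritParams isar_curve
#' @param n_sim number of null iterations (default 999).
#' @param bandwidth kernel bandwidth in meters (default 50).
#' @param cell intensity lattice cell size in meters (default 1).
#' @param edge_correct see [epanechnikov_intensity].
#' @param seed optional integer seed.
#' @return Matrix of dimension `n_sim` x `length(radii)` of null mean
#'   richness values (a row is all-`NA` when an iteration left no eligible
#'   focal); attributes `radii`, `species`, `n_sim`, `bandwidth`.
#' @export
isar_null <- function(plot, species, radii = isar_radii(), buffer = 50,
                      n_sim = 999, bandwidth = 50, cell = 1,
                      exclude_focal_species = TRUE, edge_correct = TRUE,
                      seed = NULL) {
  radii <- check_radii(radii)
  stopifnot(n_sim >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- plot$stems
  target <- st[st$species == species, , drop = FALSE]
  if (!nrow(target)) stop("species `", species, "` is absent from the plot")
  surface <- epanechnikov_intensity(target$x, target$y, plot$window,
                                    bandwidth = bandwidth, cell = cell,
                                    edge_correct = edge_correct)
  others <- st[st$species != species, , drop = FALSE]
  out <- matrix(NA_real_, n_sim, length(radii))
  for (k in seq_len(n_sim)) {
    pos <- simulate_heterogeneous_poisson(surface, nrow(target))
    elig <- edge_distance(pos$x, pos$y, plot$window) >= buffer
    if (!any(elig)) next
    foc <- pos[elig, , drop = FALSE]
    if (exclude_focal_species) {
      nb <- others
      lev <- sort(unique(nb$species))
      cnt <- richness_counts(foc, nb, lev, radii)
    } else {
      sim <- data.frame(stem_id = paste0(".sim", seq_len(nrow(pos))),
                        species = species, x = pos$x, y = pos$y)
      nb <- rbind(others[c("stem_id", "species", "x", "y")], sim)
      lev <- sort(unique(nb$species))
      skip <- match(sim$stem_id[elig], nb$stem_id)
      cnt <- richness_counts(foc, nb, lev, radii, skip)
    }
    out[k, ] <- colMeans(cnt)
  }
  structure(out, radii = radii, species = species, n_sim = n_sim,
            bandwidth = bandwidth)
}

#' Classify a species against its null ensemble
#'
#' Per-radius two-sided Monte-Carlo rank test of an observed curve against a
#' null ensemble. With `m` valid null values, the upper tail p-value is
#' `(1 + #{null >= obs}) / (m + 1)` and the lower analogously; the species is
#' an `accumulator` at a radius when the upper p-value is at most `alpha/2`
#' (with 999 nulls and `alpha = 0.05`: observed exceeds at least 975 null
#' values), a `repeller` when the lower p-value is, and `neutral` otherwise.
#' Ties between observed and null values count in both tails, breaking
#' toward neutral. `envelope = "simultaneous"` applies a Bonferroni
#' correction across radii for a conservative plot-wide designation.
#'
#' @param observed numeric vector of observed means, one per radius.
#' @param ensemble matrix from [isar_null] (or any null generator) with one
#'   column per radius.
#' @param alpha two-sided significance level (default 0.05).
#' @param envelope `"pointwise"` (default, per-scale designation) or
#'   `"simultaneous"`.
#' @return Data frame with columns `radius_m` (when the ensemble carries a
#'   `radii` attribute), `null_mean`, `null_q025`, `null_q975`, `n_valid`,
#'   `status` (factor accumulator/neutral/repeller).
#' @export
classify_status <- function(observed, ensemble, alpha = 0.05,
                            envelope = c("pointwise", "simultaneous")) {
  envelope <- match.arg(envelope)
  if (length(observed) != ncol(ensemble))
    stop("observed curve and null ensemble disagree on the radius grid")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  a <- if (envelope == "simultaneous") alpha / length(observed) else alpha
  res <- lapply(seq_along(observed), function(j) {
    vals <- ensemble[, j]
    vals <- vals[!is.na(vals)]
    m <- length(vals)
    if (m == 0L || is.na(observed[j]))
      return(data.frame(null_mean = NA_real_, null_q025 = NA_real_,
                        null_q975 = NA_real_, n_valid = m,
                        status = "neutral"))
    p_hi <- (1 + sum(vals >= observed[j])) / (m + 1)
    p_lo <- (1 + sum(vals <= observed[j])) / (m + 1)
    status <- if (p_hi <= a / 2) "accumulator"
              else if (p_lo <= a / 2) "repeller" else "neutral"
    data.frame(null_mean = mean(vals),
               null_q025 = unname(quantile(vals, 0.025)),
               null_q975 = unname(quantile(vals, 0.975)),
               n_valid = m, status = status)
  })
  res <- do.call(rbind, res)
  res$status <- factor(res$status,
                       levels = c("accumulator", "neutral", "repeller"))
  radii <- attr(ensemble, "radii")
  if (!is.null(radii)) res <- cbind(radius_m = radii, res)
  rownames(res) <- NULL
  res
}

#' Individual species-area relationships with null-model designations
#'
#' Full ISAR analysis of a mapped plot: for each focal species with at least
#' one edge-buffered individual, computes the observed mean neighborhood
#' richness curve, a heterogeneous Poisson null ensemble ([isar_null]), and
#' the per-scale accumulator/repeller/neutral designation
#' ([classify_status]). Species without eligible focals are skipped and
#' reported in the `"skipped"` attribute.
#'
#' @inheritParams isar_null
#' @inheritParams classify_status
#' @param species character vector of focal species (default: every species
#'   in the plot).
#' @return Tidy data frame: `species`, `radius_m`, `n_focals`,
#'   `obs_mean_richness`, `null_mean`, `null_q025`, `null_q975`, `status`.
#'   Attribute `"skipped"`: data frame `species`, `reason`.
#' @examples
#' \donttest{
#' plot <- generate_forest(forest_spec(n_species = 5, stems_per_species = 40,
#'                                     window = c(0, 0, 120, 120), seed = 1))
#' head(isar(plot, radii = c(5, 10), buffer = 30, n_sim = 99, seed = 1))
#' }
#' @export
isar <- function(plot, species = NULL, radii = isar_radii(), buffer = 50,
                 n_sim = 999, alpha = 0.05, bandwidth = 50, cell = 1,
                 exclude_focal_species = TRUE, edge_correct = TRUE,
                 envelope = c("pointwise", "simultaneous"), seed = NULL) {
  stopifnot(inherits(plot, "census_plot"))
  envelope <- match.arg(envelope)
  if (!is.null(seed)) set.seed(seed)
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
    obs <- isar_curve(plot, sp, radii, buffer, exclude_focal_species)
    ens <- isar_null(plot, sp, radii, buffer, n_sim, bandwidth, cell,
                     exclude_focal_species, edge_correct)
    cls <- classify_status(obs$obs_mean_richness, ens, alpha, envelope)
    rows[[sp]] <- data.frame(
      species = sp, radius_m = obs$radius_m, n_focals = obs$n_focals,
      obs_mean_richness = obs$obs_mean_richness,
      null_mean = cls$null_mean, null_q025 = cls$null_q025,
      null_q975 = cls$null_q975, status = cls$status)
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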