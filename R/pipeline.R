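status_levels <- c("accumulator", "neutral", "repeller")

#' Cross-tabulate richness and phylogenetic status at a scale
#'
#' 3 x 3 contingency table of species' richness-based (ISAR) status against
#' their PD-based (IPAR) status at one neighborhood radius, with a
#' two-tailed exact independence test. Only species present in both tables
#' at that radius enter. The test is Fisher's exact test; when the network
#' algorithm's workspace is exceeded a Monte-Carlo exact approximation
#' (10^4 table simulations) is used and reported as such. With fewer than
#' two non-empty rows or columns the test is skipped and the table still
#' returned.
#'
#' @param isar_status data frame with columns `species`, `radius_m`,
#'   `status` (e.g. from [isar]).
#' @param ipar_status likewise (e.g. from [ipar]).
#' @param radius the radius (meters) at which to tabulate.
#' @return Object of class `status_crosstab`: list with `radius_m`, `table`
#'   (3 x 3), `p_value`, `method`, `n_species`.
#' @export
cross_tabulate <- function(isar_status, ipar_status, radius) {
  a <- isar_status[isar_status$radius_m == radius, c("species", "status")]
  b <- ipar_status[ipar_status$radius_m == radius, c("species", "status")]
  if (!nrow(a) || !nrow(b))
    stop("no status calls at radius ", radius, " m")
  m <- merge(a, b, by = "species", suffixes = c("_isar", "_ipar"))
  tb <- table(isar = factor(m$status_isar, status_levels),
              ipar = factor(m$status_ipar, status_levels))
  tbt <- tb[rowSums(tb) > 0, colSums(tb) > 0, drop = FALSE]
  testable <- nrow(tbt) >= 2 && ncol(tbt) >= 2
  if (testable) {
    ft <- tryCatch(fisher.test(tbt, workspace = 2e7),
                   error = function(e)
                     fisher.test(tbt, simulate.p.value = TRUE, B = 1e4))
    p <- ft$p.value
    method <- if (grepl("simulated", ft$method)) "fisher_monte_carlo"
              else "fisher_exact"
  } else {
    p <- NA_real_
    method <- "skipped_empty_margin"
  }
  structure(list(radius_m = radius, table = tb, p_value = p,
                 method = method, n_species = nrow(m)),
            class = "status_crosstab")
}

#' @export
print.status_crosstab <- function(x, ...) {
  cat("Richness status x phylogenetic status at", x$radius_m, "m (",
      x$n_species, "species )\n")
  print(x$table)
  cat("two-tailed p =", signif(x$p_value, 3), "[", x$method, "]\n")
  invisible(x)
}

#' Phylogenetic dispersion of status groups
#'
#' NRI and NTI ([nri_nti]) of the accumulator, repeller and neutral species
#' assemblages at every radius of a status table, against tip shuffles of
#' the plot phylogeny. Groups with fewer than two members, or spanning the
#' whole phylogeny, are flagged rather than scored.
#'
#' @param tree plot phylogeny (`phylo`).
#' @param status_tab data frame with `species`, `radius_m`, `status`.
#' @param n_shuffle tip shuffles (default 999).
#' @param seed optional integer seed.
#' @return Tidy data frame: `radius_m`, `status`, `n_species`, `metric`
#'   (NRI/NTI), `value`, `obs`, `null_mean`, `null_sd`, `flag`.
#' @export
status_dispersion <- function(tree, status_tab, n_shuffle = 999,
                              seed = NULL) {
  check_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (r in sort(unique(status_tab$radius_m))) {
    at <- status_tab[status_tab$radius_m == r, ]
    for (s in status_levels) {
      sp <- unique(at$species[at$status == s])
      if (length(sp) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          radius_m = r, status = s, n_species = length(sp),
          metric = c("NRI", "NTI"), value = NA_real_, obs = NA_real_,
          null_mean = NA_real_, null_sd = NA_real_, flag = "too_few_species")
        next
      }
      nn <- nri_nti(tree, sp, n_shuffle)
      rows[[length(rows) + 1L]] <- data.frame(
        radius_m = r, status = s, n_species = length(sp),
        metric = nn$metric, value = nn$value, obs = nn$obs,
        null_mean = nn$null_mean, null_sd = nn$null_sd, flag = nn$flag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phylogenetic signal in accumulator/repeller status
#'
#' At every radius of a status table: (i) the Sankoff parsimony permutation
#' test ([sankoff_signal_test], unit costs) on the ternary
#' accumulator/neutral/repeller status of all scored species, and (ii) the
#' Fritz-Purvis D statistic ([fritz_purvis_d]) on the binary trait obtained
#' by scoring species as accumulator or repeller, neutral species excluded.
#' Scales where a statistic is undefined (constant trait, too few species)
#' are flagged.
#'
#' @inheritParams status_dispersion
#' @param n_perm_sankoff permutations for the Sankoff test (default 999).
#' @param n_perm_d permutations per null for D (default 1000).
#' @return Tidy data frame: `radius_m`, `trait`, `statistic`
#'   (`sankoff`/`D`), `value`, `p`, `p_brownian` (D only), `n_perm`,
#'   `flag`.
#' @export
status_signal <- function(tree, status_tab, n_perm_sankoff = 999,
                          n_perm_d = 1000, seed = NULL) {
  check_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  for (r in sort(unique(status_tab$radius_m))) {
    at <- status_tab[status_tab$radius_m == r, ]
    states <- setNames(as.character(at$status), at$species)
    states <- states[names(states) %in% tree$tip.label]
    if (length(states) >= 3 && length(unique(states)) >= 2) {
      tr <- ape::keep.tip(tree, names(states))
      st <- sankoff_signal_test(tr, states, n_perm = n_perm_sankoff)
      add(radius_m = r, trait = "status_ternary", statistic = "sankoff",
          value = st$score, p = st$p, p_brownian = NA_real_,
          n_perm = st$n_perm, flag = st$flag)
    } else {
      add(radius_m = r, trait = "status_ternary", statistic = "sankoff",
          value = NA_real_, p = NA_real_, p_brownian = NA_real_,
          n_perm = n_perm_sankoff, flag = "degenerate_trait")
    }
    bin <- states[states != "neutral"]
    if (length(bin) >= 2 && length(unique(bin)) == 2) {
      d <- fritz_purvis_d(ape::keep.tip(tree, names(bin)), bin,
                          n_perm = n_perm_d)
      add(radius_m = r, trait = "accumulator_repeller", statistic = "D",
          value = d$d, p = d$p_random, p_brownian = d$p_brownian,
          n_perm = d$n_perm, flag = d$flag)
    } else {
      add(radius_m = r, trait = "accumulator_repeller", statistic = "D",
          value = NA_real_, p = NA_real_, p_brownian = NA_real_,
          n_perm = n_perm_d, flag = "degenerate_trait")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

crosstab_table <- function(isar_tab, ipar_tab, radii) {
  rows <- lapply(radii, function(r) {
    ct <- cross_tabulate(isar_tab, ipar_tab, r)
    nm <- outer(status_levels, status_levels,
                function(a, b) paste0("isar_", substr(a, 1, 3), "_ipar_",
                                      substr(b, 1, 3)))
    out <- as.data.frame(as.list(as.vector(t(ct$table))))
    names(out) <- as.vector(t(nm))
    cbind(data.frame(radius_m = r, n_species = ct$n_species), out,
          data.frame(p_value = ct$p_value, method = ct$method))
  })
  do.call(rbind, rows)
}

write_tidy <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full neighborhood-diversity pipeline
#'
#' Census filters, ISAR with heterogeneous Poisson designations, IPAR with
#' S.E.S. PD designations, NRI/NTI dispersion of the status groups, Sankoff
#' and D phylogenetic-signal tests, and the richness x phylogenetic status
#' cross-tabulation — end to end, under one seed. Species dropped at any
#' stage (filters, missing phylogeny tips, no eligible focal) are collected
#' in a sidecar table. When `config$out_dir` is set, every table is written
#' as tab-separated text re-readable by [read.table], together with a JSON
#' run manifest (package/R versions, config echo, per-stage timings).
#'
#' @param config an [analysis_config].
#' @param plot optional [census_plot] (otherwise read from
#'   `config$census`).
#' @param tree optional `phylo` (otherwise read from `config$tree`).
#' @return List with elements `isar`, `ipar`, `dispersion`, `signal`,
#'   `crosstab`, `skipped`, `manifest`.
#' @export
run_pipeline <- function(config, plot = NULL, tree = NULL) {
  stopifnot(inherits(config, "canopyphy_config"))
  if (is.null(plot)) {
    if (is.null(config$census)) stop("no census: set config$census or pass `plot`")
    plot <- read_census(config$census)
  }
  if (is.null(tree)) {
    if (is.null(config$tree)) stop("no phylogeny: set config$tree or pass `tree`")
    tree <- read_tree(config$tree)
  }
  set.seed(config$seed)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }
  plot <- stage("filter", apply_filters(plot, config$dbh_min,
                                        config$abundance_min))
  skipped <- attr(plot, "dropped")
  missing_tips <- setdiff(unique(plot$stems$species), tree$tip.label)
  if (length(missing_tips)) {
    warning("dropping ", length(missing_tips),
            " species without a phylogeny tip: ",
            paste(missing_tips, collapse = ", "))
    skipped <- rbind(skipped, data.frame(species = missing_tips,
                                         reason = "missing phylogeny tip"))
    st <- plot$stems[!plot$stems$species %in% missing_tips, , drop = FALSE]
    plot <- census_plot(st, plot$window)
  }
  tree <- prune_to_plot(tree, sort(unique(plot$stems$species)))
  isar_tab <- stage("isar",
    isar(plot, radii = config$isar_radii, buffer = config$buffer,
         n_sim = config$n_sim, alpha = config$alpha,
         bandwidth = config$bandwidth, cell = config$cell,
         exclude_focal_species = config$exclude_focal_species))
  ipar_tab <- stage("ipar",
    ipar(plot, tree, radii = config$ipar_radii, buffer = config$buffer,
         n_shuffle = config$n_shuffle, alpha = config$alpha,
         exclude_focal_species = config$exclude_focal_species,
         rooted = config$rooted))
  skipped <- rbind(skipped, attr(isar_tab, "skipped"))
  disp <- stage("dispersion",
    status_dispersion(tree, isar_tab, n_shuffle = config$n_shuffle))
  sig <- stage("signal",
    status_signal(tree, isar_tab, n_perm_sankoff = config$n_shuffle,
                  n_perm_d = config$n_perm))
  shared <- intersect(config$isar_radii, config$ipar_radii)
  ct <- stage("crosstab", crosstab_table(isar_tab, ipar_tab, shared))
  manifest <- list(
    package = "canopyphy",
    version = as.character(packageVersion("canopyphy")),
    r_version = R.version.string,
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    seed = config$seed,
    config = unclass(config),
    n_stems = nrow(plot$stems),
    n_species = length(unique(plot$stems$species)),
    n_tips = length(tree$tip.label),
    stage_seconds = as.list(timings))
  out <- list(isar = isar_tab, ipar = ipar_tab, dispersion = disp,
              signal = sig, crosstab = ct, skipped = skipped,
              manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("isar", "ipar", "dispersion", "signal", "crosstab",
                 "skipped"))
      write_tidy(out[[nm]], config$out_dir, nm)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
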