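sniff_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Read and write mapped census tables
#'
#' Delimited text with header columns `stem_id, species, x, y, dbh`
#' (coordinates in meters, dbh in cm); comma and tab dialects are detected
#' from the header. An optional leading comment of the form
#' `# window: xmin ymin xmax ymax` records the plot window; without it (and
#' without the `window` argument) the bounding box of the stems is used,
#' with a message. [write_census] always writes the window comment, so
#' write/read round-trips reproduce the plot exactly.
#'
#' @param path file path.
#' @param window optional `c(xmin, ymin, xmax, ymax)` override.
#' @return [read_census]: a [census_plot]. [write_census]: `path`,
#'   invisibly.
#' @export
read_census <- function(path, window = NULL) {
  lines <- readLines(path, n = 5L)
  if (!length(lines)) stop("empty census file: ", path)
  wline <- grep("^#\\s*window:", lines, value = TRUE)
  if (is.null(window) && length(wline)) {
    window <- as.numeric(strsplit(sub("^#\\s*window:\\s*", "", wline[1]),
                                  "[,; ]+")[[1]])
    if (length(window) != 4 || anyNA(window))
      stop("malformed `# window:` comment in ", path)
  }
  hdr <- lines[!startsWith(lines, "#")][1]
  sep <- sniff_sep(hdr)
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("stem_id", "species", "x", "y", "dbh")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("census file lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(window)) {
    window <- c(floor(min(df$x)), floor(min(df$y)),
                ceiling(max(df$x)), ceiling(max(df$y)))
    message("no window given; using the stems' bounding box [",
            paste(window, collapse = ", "), "]")
  }
  plot <- census_plot(df, window)
  message("read ", nrow(plot$stems), " stems of ",
          length(unique(plot$stems$species)), " species from ", path)
  plot
}

#' @rdname read_census
#' @param plot a [census_plot].
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @export
write_census <- function(plot, path, sep = ",") {
  stopifnot(inherits(plot, "census_plot"), sep %in% c(",", "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# window:", paste(format(plot$window, trim = TRUE,
                                             digits = 15), collapse = " ")),
             con)
  write.table(plot$stems, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plot phylogeny from Newick
#'
#' Thin wrapper over [ape::read.tree] that enforces the package's contract:
#' rooted, branch lengths present and non-negative, unique tip labels
#' (polytomies are allowed).
#'
#' @param path Newick file path.
#' @return A validated `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse a Newick tree from ", path)
  check_phylogeny(tree)
  message("read phylogeny with ", length(tree$tip.label), " tips from ", path)
  tree
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with the standard defaults: all
#' stems >= 1 cm dbh, no abundance filter, 1-50 m richness radii and the
#' sparser PD grid, 50 m edge buffer, 50 m kernel bandwidth, 999 null
#' iterations and tip shuffles, 1000 permutations for the D statistic,
#' two-sided alpha 0.05. Configurations round-trip through YAML via
#' [write_config] / [read_config].
#'
#' @param census,tree,out_dir optional paths (census table, Newick tree,
#'   output directory).
#' @param dbh_min,abundance_min census filters, see [apply_filters].
#' @param isar_radii,ipar_radii radius grids in meters.
#' @param buffer edge buffer in meters.
#' @param alpha two-sided significance level in (0, 0.5).
#' @param bandwidth,cell intensity-estimate parameters in meters.
#' @param n_sim heterogeneous Poisson iterations.
#' @param n_shuffle tip shuffles for PD/dispersion nulls.
#' @param n_perm permutations for the D statistic and Sankoff test.
#' @param exclude_focal_species,rooted conventions, see [isar_curve] and
#'   [faith_pd].
#' @param seed integer seed for the whole pipeline.
#' @return List of class `canopyphy_config`.
#' @export
analysis_config <- function(census = NULL, tree = NULL, out_dir = NULL,
                            dbh_min = 1, abundance_min = 0,
                            isar_radii = canopyphy::isar_radii(),
                            ipar_radii = canopyphy::ipar_radii(),
                            buffer = 50, alpha = 0.05, bandwidth = 50,
                            cell = 1, n_sim = 999, n_shuffle = 999,
                            n_perm = 1000, exclude_focal_species = TRUE,
                            rooted = TRUE, seed = 1) {
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  if (any(c(n_sim, n_shuffle, n_perm) < 1) || buffer < 0 || bandwidth <= 0 ||
      cell <= 0 || dbh_min < 0 || abundance_min < 0)
    stop("counts and scales must be positive")
  structure(list(census = census, tree = tree, out_dir = out_dir,
                 dbh_min = dbh_min, abundance_min = abundance_min,
                 isar_radii = check_radii(isar_radii),
                 ipar_radii = check_radii(ipar_radii),
                 buffer = buffer, alpha = alpha, bandwidth = bandwidth,
                 cell = cell, n_sim = n_sim, n_shuffle = n_shuffle,
                 n_perm = n_perm,
                 exclude_focal_species = exclude_focal_species,
                 rooted = rooted, seed = as.integer(seed)),
            class = "canopyphy_config")
}

#' @rdname analysis_config
#' @param config a `canopyphy_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "canopyphy_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}
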