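#' Assemble and validate an analysis configuration
#'
#' Collects every tunable of the end-to-end analysis. Subsets are
#' configuration, not code: each named subset lists the subpopulations it
#' keeps, and the outgroup must be present in every subset (it is retained
#' in all leave-one-out evaluations).
#'
#' @param outgroup Outgroup subpopulation label, or `NULL`.
#' @param subsets Named list: subset label -> character vector of
#'   subpopulation labels (the whole set is always analyzed and need not be
#'   listed).
#' @param min_n Minimum subpopulation sample size (default 6).
#' @param fis_threshold Null-allele FIS screen threshold (default 0.9).
#' @param pcrit LD-method minor-allele-frequency screen (default 0.05).
#' @param prune_window,prune_step,prune_r2 LD pruning parameters
#'   (defaults 50, 10, 0.2).
#' @param g Rarefaction size override, or `NULL` for automatic.
#' @param pca_components Components reported by the PCA (default 10).
#' @param size_scheme Sample-size classification scheme for the sign
#'   association test (see [classify_signs()]).
#' @param seed Integer seed recorded in the manifest.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(outgroup = NULL, subsets = list(),
                            min_n = 6L, fis_threshold = 0.9,
                            pcrit = 0.05, prune_window = 50L,
                            prune_step = 10L, prune_r2 = 0.2,
                            g = NULL, pca_components = 10L,
                            size_scheme = "lt10", seed = 1L) {
  if (length(subsets) && is.null(names(subsets)))
    stop("subsets must be a named list")
  structure(list(outgroup = outgroup, subsets = subsets, min_n = min_n,
                 fis_threshold = fis_threshold, pcrit = pcrit,
                 prune_window = prune_window, prune_step = prune_step,
                 prune_r2 = prune_r2, g = g,
                 pca_components = pca_components,
                 size_scheme = size_scheme, seed = as.integer(seed)),
            class = "analysis_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full diversity-reservoir analysis
#'
#' Orchestrates the end-to-end pipeline on one dataset: cohort filters
#' (minimum sample size, FIS null-allele screen), diversity partitions and
#' leave-one-out contributions for the whole set and every configured
#' subset (outgroup always retained), LD pruning and per-subpopulation Ne
#' by both molecular methods, genotype PCA with subpopulation means, and
#' the downstream association statistics. All outputs are TSV plus one
#' JSON manifest.
#'
#' @param gm A [geno_matrix()].
#' @param subs A [subpop_map()]; its outgroup must match the config.
#' @param cfg An [analysis_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return Invisibly, a list (`report bundle`) with elements
#'   `contributions` (named list of [marginal_contributions()] tables, one
#'   per analysis set), `ne`, `pca`, `signs`, `cmh`, `correlations`,
#'   `consistency`, `filters` and `manifest`.
#' @export
run_full_analysis <- function(gm, subs, cfg = analysis_config(),
                              out_dir = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  check_assignment(gm, subs)
  og <- cfg$outgroup
  if (!is.null(og) && (is.null(subs$outgroup) || subs$outgroup != og))
    stop("config outgroup does not match the subpopulation map")
  if (is.null(og)) og <- subs$outgroup
  for (nm in names(cfg$subsets)) {
    bad <- setdiff(cfg$subsets[[nm]], unique(subs$assignment))
    if (length(bad))
      stop("subset '", nm, "' references unknown subpopulations: ",
           paste(bad, collapse = ", "))
    if (!is.null(og) && !og %in% cfg$subsets[[nm]])
      stop("subset '", nm, "' must retain the outgroup '", og, "'")
  }
  filters <- list()
  fs <- filter_small_subpopulations(gm, subs, min_n = cfg$min_n)
  filters$small_subpops <- fs$removed
  fn <- filter_null_allele_loci(fs$geno, fs$subs,
                                threshold = cfg$fis_threshold)
  filters$null_loci <- fn$removed
  gm <- fn$geno
  subs <- fs$subs
  counts <- count_alleles(gm, subs)
  sets <- c(list(whole = subpop_labels(subs)),
            lapply(cfg$subsets, intersect, y = subpop_labels(subs)))
  contributions <- lapply(sets, function(labs)
    marginal_contributions(counts, included = labs, outgroup = og,
                           g = cfg$g))
  panel <- ld_prune(gm, window = cfg$prune_window, step = cfg$prune_step,
                    r2max = cfg$prune_r2)
  ne <- ne_table(gm, subs, panel = panel, pcrit = cfg$pcrit)
  pca <- pca_genotypes(gm, m = cfg$pca_components, subs = subs)
  signs <- classify_signs(contributions$whole,
                          size_scheme = cfg$size_scheme)
  cmh <- tryCatch(cmh_test(unclass(signs$xtab)),
                  error = function(e) list(statistic = NA_real_,
                                           df = NA_real_,
                                           p.value = NA_real_,
                                           note = conditionMessage(e)))
  correlations <- NULL
  if (!is.null(ne)) {
    mm <- merge(ne[ne$method == "LD", c("subpopulation", "point")],
                ne[ne$method == "coancestry", c("subpopulation", "point")],
                by = "subpopulation")
    correlations <- tryCatch(paired_correlations(mm$point.x, mm$point.y),
                             error = function(e) NULL)
  }
  consistency <- lapply(contributions[-1], function(ct)
    consistency_report(contributions$whole, ct))
  manifest <- list(package = "metapopdiv",
                   version = as.character(utils::packageVersion("metapopdiv")),
                   seed = cfg$seed,
                   n_individuals = nrow(gm$dose), n_loci = ncol(gm$dose),
                   n_subpops = length(subpop_labels(subs)),
                   outgroup = if (is.null(og)) NA else og,
                   g = contributions$whole$g[1],
                   pruned_retained = length(panel$retained),
                   config = unclass(cfg))
  bundle <- list(contributions = contributions, ne = ne, pca = pca,
                 signs = signs, cmh = cmh, correlations = correlations,
                 consistency = consistency, filters = filters,
                 manifest = manifest, panel = panel)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(contributions))
      write_tsv(as.data.frame(contributions[[nm]]),
                file.path(out_dir, paste0("contributions_", nm, ".tsv")))
    if (!is.null(ne)) write_tsv(ne, file.path(out_dir, "ne.tsv"))
    eig <- data.frame(individual = rownames(pca$vectors),
                      subpopulation = subs$assignment[rownames(pca$vectors)],
                      pca$vectors, stringsAsFactors = FALSE)
    write_tsv(eig, file.path(out_dir, "pca_eigenvectors.tsv"))
    write_tsv(data.frame(subpopulation = rownames(pca$subpop_means),
                         pca$subpop_means),
              file.path(out_dir, "pca_subpop_means.tsv"))
    write_tsv(signs$table, file.path(out_dir, "sign_classification.tsv"))
    stats_tab <- data.frame(
      test = c("cmh", "pearson_ne", "spearman_ne"),
      statistic = c(cmh$statistic,
                    if (is.null(correlations)) NA else correlations$pearson,
                    if (is.null(correlations)) NA else correlations$spearman),
      p_value = c(cmh$p.value,
                  if (is.null(correlations)) NA else correlations$p_pearson,
                  if (is.null(correlations)) NA else correlations$p_spearman))
    write_tsv(stats_tab, file.path(out_dir, "association_stats.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}

#' Rank consistency of contributions between two analysis sets
#'
#' Spearman and Pearson correlations of the total contributions (`cHT`,
#' `cAT`) across the targets common to a whole-set and a subset analysis —
#' the check that subsetting preserves the ranking of contributors.
#'
#' @param whole,subset Two [marginal_contributions()] tables.
#' @return Data frame with one row per parameter (`cHT`, `cAT`):
#'   `spearman`, `pearson` and `n_common`.
#' @export
consistency_report <- function(whole, subset) {
  common <- intersect(whole$subpopulation, subset$subpopulation)
  if (length(common) < 3L)
    stop("need at least 3 common targets, found ", length(common))
  iw <- match(common, whole$subpopulation)
  is_ <- match(common, subset$subpopulation)
  out <- lapply(c("cHT", "cAT"), function(par) {
    pc <- paired_correlations(whole[[par]][iw], subset[[par]][is_])
    data.frame(parameter = par, spearman = pc$spearman,
               pearson = pc$pearson, n_common = pc$n_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
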