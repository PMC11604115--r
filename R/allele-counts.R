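#' Count allele copies per subpopulation and locus
#'
#' Tallies reference-allele copies and total observed gene copies for every
#' (subpopulation, locus) cell. Frequencies are always computed over the
#' observed copies only (complete cases per locus per subpopulation);
#' `copies_total` is twice the number of non-missing individuals.
#'
#' @param gm A [geno_matrix()].
#' @param subs A [subpop_map()] covering every individual of `gm`.
#' @return An object of class `allele_counts`: list with integer matrices
#'   `ref` and `total` (subpopulations x loci, dimnames set), the locus
#'   table, and `sizes` (individuals per subpopulation).
#' @export
#' @examples
#' gm <- geno_matrix(matrix(c(0L, 1L, 2L), 3, 1,
#'                          dimnames = list(c("a", "b", "c"), "rs1")),
#'                   loci_table("rs1"))
#' subs <- subpop_map(c(a = "P1", b = "P1", c = "P1"))
#' allele_freq(count_alleles(gm, subs))   # p = 0.5
count_alleles <- function(gm, subs) {
  check_assignment(gm, subs)
  labs <- subpop_labels(subs)
  grp <- factor(subs$assignment[individual_ids(gm)], levels = labs)
  d0 <- gm$dose
  obs <- !is.na(d0)
  d0[!obs] <- 0L
  ref <- rowsum(d0, grp)
  total <- 2L * rowsum(obs + 0L, grp)
  storage.mode(ref) <- "integer"
  storage.mode(total) <- "integer"
  dimnames(ref) <- dimnames(total) <- list(labs, gm$loci$id)
  structure(list(ref = ref, total = total, loci = gm$loci,
                 sizes = stats::setNames(as.integer(table(grp)[labs]), labs)),
            class = "allele_counts")
}

#' Construct allele counts directly
#'
#' Builds the `allele_counts` container from copy-number matrices, for
#' workflows that start from frequency tables rather than genotypes.
#'
#' @param ref,total Integer matrices (subpopulations x loci) of
#'   reference-allele copies and total observed copies; `total` must be
#'   even with `0 <= ref <= total`.
#' @param loci Optional locus table (see [loci_table()]); defaults to
#'   generic ids.
#' @param sizes Optional named integer vector of individuals per
#'   subpopulation; defaults to `max(total) / 2` per subpopulation.
#' @return An `allele_counts` object.
#' @export
allele_counts <- function(ref, total, loci = NULL, sizes = NULL) {
  ref <- as.matrix(ref); total <- as.matrix(total)
  stopifnot(all(dim(ref) == dim(total)), all(ref >= 0, na.rm = TRUE),
            all(ref <= total, na.rm = TRUE),
            all(total %% 2 == 0, na.rm = TRUE))
  storage.mode(ref) <- "integer"
  storage.mode(total) <- "integer"
  if (is.null(rownames(ref)))
    rownames(ref) <- rownames(total) <- paste0("pop", seq_len(nrow(ref)))
  if (is.null(loci)) loci <- loci_table(paste0("L", seq_len(ncol(ref))))
  colnames(ref) <- colnames(total) <- loci$id
  if (is.null(sizes))
    sizes <- stats::setNames(as.integer(apply(total, 1L, max) / 2),
                             rownames(ref))
  structure(list(ref = ref, total = total, loci = loci, sizes = sizes),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %d subpopulations x %d loci\n",
              nrow(x$ref), ncol(x$ref)))
  invisible(x)
}

#' Reference-allele frequencies
#'
#' @param counts An [count_alleles()] result.
#' @return Matrix of reference-allele frequencies (subpopulations x loci);
#'   `NaN` where a subpopulation has no observed copies at a locus.
#' @export
allele_freq <- function(counts) counts$ref / counts$total

#' Restrict allele counts to a set of subpopulations
#' @param counts An `allele_counts` object.
#' @param subpops Labels to keep, in the order given.
#' @return An `allele_counts` object with the requested rows.
#' @export
subset_counts <- function(counts, subpops) {
  missing_labs <- setdiff(subpops, rownames(counts$ref))
  if (length(missing_labs))
    stop("unknown subpopulations: ", paste(missing_labs, collapse = ", "))
  structure(list(ref = counts$ref[subpops, , drop = FALSE],
                 total = counts$total[subpops, , drop = FALSE],
                 loci = counts$loci, sizes = counts$sizes[subpops]),
            class = "allele_counts")
}

#' Per-subpopulation, per-locus FIS (heterozygote deficit)
#'
#' Plug-in estimator `FIS = 1 - Ho/He` with `Ho` the observed heterozygote
#' proportion among non-missing individuals and `He = 2 p (1 - p)` from the
#' plug-in allele frequency. Values near 1 flag null-allele or genotyping
#' artifacts. Undefined (NA) where a locus is monomorphic in a
#' subpopulation or has no observed genotypes there.
#'
#' @inheritParams count_alleles
#' @return Numeric matrix (subpopulations x loci) of FIS values with `NA`
#'   where undefined.
#' @export
locus_fis <- function(gm, subs) {
  check_assignment(gm, subs)
  labs <- subpop_labels(subs)
  grp <- factor(subs$assignment[individual_ids(gm)], levels = labs)
  obs <- !is.na(gm$dose)
  het <- gm$dose == 1L
  het[!obs] <- FALSE
  n_obs <- rowsum(obs + 0L, grp)
  n_het <- rowsum(het + 0L, grp)
  d0 <- gm$dose
  d0[!obs] <- 0L
  p <- rowsum(d0, grp) / (2 * n_obs)
  ho <- n_het / n_obs
  he <- 2 * p * (1 - p)
  fis <- 1 - ho / he
  fis[!is.finite(fis)] <- NA_real_
  fis[n_obs == 0] <- NA_real_
  dimnames(fis) <- list(labs, gm$loci$id)
  fis
}

#' Remove loci showing extreme heterozygote deficit (null-allele screen)
#'
#' A locus is removed when its FIS exceeds `threshold` (strictly) in any
#' assessed subpopulation — the screen for null and partially null alleles
#' in populations without pedigrees. Undefined FIS values never trigger
#' removal.
#'
#' @inheritParams count_alleles
#' @param threshold FIS threshold in (0, 1]; default 0.9.
#' @param subpops Subpopulations to assess (default: all).
#' @return List with `geno` (filtered [geno_matrix()]) and `removed`
#'   (data frame: `locus`, `subpop`, `fis` of the triggering cell).
#' @export
filter_null_allele_loci <- function(gm, subs, threshold = 0.9,
                                    subpops = NULL) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  fis <- locus_fis(gm, subs)
  if (!is.null(subpops)) fis <- fis[subpops, , drop = FALSE]
  hit <- fis > threshold
  hit[is.na(hit)] <- FALSE
  drop_locus <- colSums(hit) > 0L
  removed <- data.frame(locus = character(), subpop = character(),
                        fis = numeric(), stringsAsFactors = FALSE)
  if (any(drop_locus)) {
    trig <- apply(hit[, drop_locus, drop = FALSE], 2L, which.max)
    removed <- data.frame(
      locus = colnames(fis)[drop_locus],
      subpop = rownames(fis)[trig],
      fis = fis[cbind(trig, which(drop_locus))],
      stringsAsFactors = FALSE)
  }
  if (all(drop_locus)) stop("null-allele screen removed every locus")
  geno <- if (any(drop_locus))
    subset_geno(gm, loci = gm$loci$id[!drop_locus]) else gm
  list(geno = geno, removed = removed)
}

#' Drop subpopulations below a minimum sample size
#'
#' Cohort-assembly filter: subpopulations with fewer than `min_n`
#' individuals are removed together with their individuals. The outgroup
#' pool can be exempted.
#'
#' @inheritParams count_alleles
#' @param min_n Minimum individuals per retained subpopulation (default 6).
#' @param exempt_outgroup Keep the outgroup regardless of size?
#' @return List with `geno`, `subs` (both filtered) and `removed`
#'   (data frame: `subpop`, `n`).
#' @export
filter_small_subpopulations <- function(gm, subs, min_n = 6L,
                                        exempt_outgroup = TRUE) {
  stopifnot(min_n >= 1L)
  check_assignment(gm, subs)
  sizes <- subpop_sizes(subs)
  small <- names(sizes)[sizes < min_n]
  if (exempt_outgroup && !is.null(subs$outgroup))
    small <- setdiff(small, subs$outgroup)
  keep <- setdiff(names(sizes), small)
  if (!length(keep)) stop("no subpopulations remain after size filter")
  removed <- data.frame(subpop = small, n = unname(sizes[small]),
                        stringsAsFactors = FALSE)
  subs2 <- subset_subpops(subs, subpops = keep)
  gm2 <- subset_geno(gm, individuals = names(subs2$assignment))
  list(geno = gm2, subs = subs2, removed = removed)
}

#' Merge subpopulations under new labels
#'
#' Rewrites the assignment so that each old label in `merge_spec` maps to
#' its new label; used to pool samples of one breed from several sources,
#' or to pool breeds by geographical area for descriptive analyses. The
#' outgroup flag of a merged pool is the OR of its parts; merging an
#' outgroup pool with a non-outgroup pool is refused as ambiguous.
#'
#' @param subs A [subpop_map()].
#' @param merge_spec Named character vector: old label -> new label.
#' @return A [subpop_map()] with rewritten assignment.
#' @export
merge_subpopulations <- function(subs, merge_spec) {
  old <- names(merge_spec)
  labs <- unique(unname(subs$assignment))
  absent <- setdiff(old, labs)
  if (length(absent))
    stop("merge_spec names absent subpopulations: ",
         paste(absent, collapse = ", "))
  a <- subs$assignment
  idx <- a %in% old
  a[idx] <- unname(merge_spec[a[idx]])
  og <- subs$outgroup
  if (!is.null(og)) {
    for (new in unique(merge_spec)) {
      parts <- c(old[merge_spec == new], new)
      in_og <- og %in% parts
      if (in_og) {
        non_og_parts <- setdiff(intersect(parts, labs), og)
        if (length(non_og_parts))
          stop("refusing to merge outgroup '", og,
               "' with non-outgroup pools: ambiguous role")
        og <- new
      }
    }
  }
  subpop_map(a, outgroup = og, group = subs$group, continent = subs$continent)
}
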