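## Metapopulation diversity partitions
##
## Gene diversity:  HT = HS + DG, with HS the equal-weight mean of the
## per-subpopulation expected heterozygosities and DG the mean of Nei's
## minimum distance over all ordered subpopulation pairs (self-pairs
## contribute 0).  Allelic richness:  AT = AS + DA, with AS the mean
## rarefacted number of segregating alleles minus one and DA the mean
## rarefacted count of alleles present in one subpopulation's sample and
## absent from another's.  Equal subpopulation weights throughout, so that
## HT equals the gene diversity of the equal-weight pooled frequencies.

usable_gene <- function(counts, included) {
  counts$total[included, , drop = FALSE] > 0L
}

#' Within-subpopulation gene diversity
#'
#' Per-subpopulation mean expected heterozygosity: the mean over usable loci
#' (loci with at least one observed gene copy in that subpopulation) of
#' `1 - sum(p_a^2)`. Plug-in frequencies, no small-sample correction, so the
#' partition identities hold exactly.
#'
#' @param counts An [count_alleles()] result.
#' @param included Subpopulation labels to evaluate (default: all).
#' @return Named numeric vector `HS_i` in `[0, 0.5]` for biallelic loci.
#' @export
gene_diversity_within <- function(counts, included = rownames(counts$ref)) {
  cc <- subset_counts(counts, included)
  use <- cc$total > 0L
  if (any(rowSums(use) == 0L))
    stop("subpopulation(s) with no usable loci: ",
         paste(included[rowSums(use) == 0L], collapse = ", "))
  p <- cc$ref / cc$total
  h <- 1 - p^2 - (1 - p)^2
  h[!use] <- NA_real_
  rowMeans(h, na.rm = TRUE)
}

#' Nei's minimum genetic distance between two subpopulations
#'
#' Mean over shared usable loci of half the summed squared allele-frequency
#' differences; for biallelic loci this is `(p_i - p_j)^2` per locus.
#'
#' @inheritParams gene_diversity_within
#' @param i,j Subpopulation labels.
#' @return Scalar distance `>= 0`; 0 when `i == j`.
#' @export
nei_minimum_distance <- function(counts, i, j) {
  if (identical(i, j)) return(0)
  cc <- subset_counts(counts, c(i, j))
  use <- cc$total[1, ] > 0L & cc$total[2, ] > 0L
  if (!any(use)) stop("no shared usable locus between ", i, " and ", j)
  p <- cc$ref / cc$total
  mean((p[1, use] - p[2, use])^2)
}

nei_distance_matrix <- function(counts, included) {
  cc <- subset_counts(counts, included)
  n <- length(included)
  p <- cc$ref / cc$total
  use <- cc$total > 0L
  if (all(use)) {
    G <- tcrossprod(p) / ncol(p)
    m2 <- diag(G)
    D <- outer(m2, rep(1, n)) + outer(rep(1, n), m2) - 2 * G
  } else {
    D <- matrix(0, n, n)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      ok <- use[a, ] & use[b, ]
      if (!any(ok))
        stop("no shared usable locus between ", included[a], " and ",
             included[b])
      D[a, b] <- D[b, a] <- mean((p[a, ok] - p[b, ok])^2)
    }
  }
  diag(D) <- 0
  dimnames(D) <- list(included, included)
  D
}

#' Partition total gene diversity into within and between components
#'
#' Computes `HS` (equal-weight mean of [gene_diversity_within()]), `DG`
#' (mean of the pairwise Nei minimum distances over all `n^2` ordered pairs,
#' self-pairs contributing zero) and `HT = HS + DG`. With complete data `HT`
#' equals the gene diversity of the equal-weight pooled allele frequencies.
#'
#' @inheritParams gene_diversity_within
#' @return An object of class `gene_div_partition`: list with `HS_i`, `D`
#'   (distance matrix), `HS`, `DG`, `HT` and `included`.
#' @export
gene_diversity_partition <- function(counts,
                                     included = rownames(counts$ref)) {
  if (length(included) < 2L)
    stop("gene diversity partition needs at least 2 subpopulations")
  HS_i <- gene_diversity_within(counts, included)
  D <- nei_distance_matrix(counts, included)
  HS <- mean(HS_i)
  DG <- mean(D)
  structure(list(HS_i = HS_i, D = D, HS = HS, DG = DG, HT = HS + DG,
                 included = included),
            class = "gene_div_partition")
}

#' @export
print.gene_div_partition <- function(x, ...) {
  cat(sprintf("<gene diversity partition> %d subpopulations\n",
              length(x$included)))
  cat(sprintf("  HS = %.6f  DG = %.6f  HT = %.6f\n", x$HS, x$DG, x$HT))
  invisible(x)
}

#' Choose the rarefaction size g
#'
#' The common number of gene copies to which every subpopulation is
#' down-sampled for fair allele counting: the minimum observed
#' `copies_total` over the included subpopulations and their usable loci.
#'
#' @inheritParams gene_diversity_within
#' @return Even integer `g >= 2`.
#' @export
choose_rarefaction_size <- function(counts,
                                    included = rownames(counts$ref)) {
  cells <- counts$total[included, , drop = FALSE]
  pos <- cells[cells > 0L]
  if (!length(pos)) stop("no usable subpopulation-locus cells")
  g <- min(pos)
  if (g < 2L) stop("rarefaction size below 2; exclude cells with <2 copies")
  as.integer(g)
}

#' Expected number of distinct alleles in a rarefacted sample
#'
#' Hypergeometric rarefaction: for allele copy numbers `N_a` summing to `N`,
#' the expected number of distinct alleles among `g` copies drawn without
#' replacement is `sum_a [1 - C(N - N_a, g) / C(N, g)]`. Computed in
#' log-space for numerical safety.
#'
#' @param copies Integer vector of copy numbers per allele.
#' @param g Rarefaction size, `2 <= g <= sum(copies)`.
#' @return Expected distinct-allele count in `[1, length(copies)]`.
#' @export
#' @examples
#' rarefacted_allele_count(c(3, 1), 2)  # 1.5
rarefacted_allele_count <- function(copies, g) {
  N <- sum(copies)
  if (g > N) stop("rarefaction size g exceeds total copies")
  if (g < 2L) stop("rarefaction size must be >= 2")
  Q <- exp(lchoose(N - copies, g) - lchoose(N, g))
  sum(1 - Q)
}

## probability an allele with Na copies out of N is unseen in a g-copy sample
unseen_prob <- function(N, Na, g) {
  exp(lchoose(N - Na, g) - lchoose(N, g))
}

#' Expected alleles sampled in one subpopulation but absent from another
#'
#' For independent g-copy rarefacted samples from subpopulations `i` and
#' `j`, returns `sum_a (1 - Q_ia) * Q_ja`, where `Q_xa` is the probability
#' that allele `a` is unseen in the sample from `x`.
#'
#' @param copies_i,copies_j Integer vectors of per-allele copy numbers in
#'   the two subpopulations (same allele order).
#' @param g Rarefaction size, at most each subpopulation's total.
#' @return Expected count of alleles present in `i`'s sample and absent
#'   from `j`'s.
#' @export
rarefacted_absent_count <- function(copies_i, copies_j, g) {
  Ni <- sum(copies_i); Nj <- sum(copies_j)
  if (g > Ni || g > Nj) stop("g exceeds a subpopulation's total copies")
  Qi <- unseen_prob(Ni, copies_i, g)
  Qj <- unseen_prob(Nj, copies_j, g)
  sum((1 - Qi) * Qj)
}

## Q matrices for ref and alt alleles over usable loci; S x L each
rarefaction_Q <- function(cc, g) {
  N <- cc$total
  list(ref = unseen_prob(N, cc$ref, g),
       alt = unseen_prob(N, N - cc$ref, g))
}

#' Partition total allelic richness into within and between components
#'
#' `AS_i` is the per-subpopulation mean (over usable loci) of the rarefacted
#' allele count minus one; `AS` its equal-weight mean. `d_ij` is the
#' symmetrized mean rarefacted count of alleles present in one
#' subpopulation's g-copy sample and absent from the other's; `DA` the mean
#' of `d` over all `n^2` ordered pairs (zero diagonal). `AT = AS + DA`.
#' Loci for which any included subpopulation has fewer than `g` observed
#' copies are excluded (and reported).
#'
#' @inheritParams gene_diversity_within
#' @param g Rarefaction size; default [choose_rarefaction_size()].
#' @return An object of class `allelic_partition`: list with `g`, `AS_i`,
#'   `d`, `AS`, `DA`, `AT`, `P_i` (private-allele richness), `included`,
#'   and `excluded_loci`.
#' @export
allelic_richness_partition <- function(counts,
                                       included = rownames(counts$ref),
                                       g = NULL) {
  if (length(included) < 2L)
    stop("allelic richness partition needs at least 2 subpopulations")
  if (is.null(g)) g <- choose_rarefaction_size(counts, included)
  cc <- subset_counts(counts, included)
  ok <- colSums(cc$total >= g) == length(included)
  excluded <- cc$loci$id[!ok]
  if (!any(ok)) stop("no locus has >= g observed copies in every subpopulation")
  cc$ref <- cc$ref[, ok, drop = FALSE]
  cc$total <- cc$total[, ok, drop = FALSE]
  n <- length(included)
  L <- ncol(cc$ref)
  Q <- rarefaction_Q(cc, g)
  AS_i <- rowMeans((1 - Q$ref) + (1 - Q$alt)) - 1
  V <- (tcrossprod(1 - Q$ref, Q$ref) + tcrossprod(1 - Q$alt, Q$alt)) / L
  d <- (V + t(V)) / 2
  diag(d) <- 0
  dimnames(d) <- list(included, included)
  ## private richness: alleles seen in i's sample, unseen in every other's
  logQr <- log(Q$ref); logQa <- log(Q$alt)
  sum_r <- colSums(logQr); sum_a <- colSums(logQa)
  P_i <- numeric(n)
  for (i in seq_len(n)) {
    others_r <- exp(sum_r - logQr[i, ])
    others_a <- exp(sum_a - logQa[i, ])
    zr <- logQr[i, ] == -Inf
    za <- logQa[i, ] == -Inf
    if (any(zr)) others_r[zr] <- exp(colSums(logQr[-i, zr, drop = FALSE]))
    if (any(za)) others_a[za] <- exp(colSums(logQa[-i, za, drop = FALSE]))
    P_i[i] <- mean((1 - Q$ref[i, ]) * others_r + (1 - Q$alt[i, ]) * others_a)
  }
  names(P_i) <- names(AS_i) <- included
  AS <- mean(AS_i)
  DA <- mean(d)
  structure(list(g = as.integer(g), AS_i = AS_i, d = d, AS = AS, DA = DA,
                 AT = AS + DA, P_i = P_i, included = included,
                 excluded_loci = excluded),
            class = "allelic_partition")
}

#' @export
print.allelic_partition <- function(x, ...) {
  cat(sprintf("<allelic richness partition> %d subpopulations, g = %d\n",
              length(x$included), x$g))
  cat(sprintf("  AS = %.6f  DA = %.6f  AT = %.6f\n", x$AS, x$DA, x$AT))
  invisible(x)
}

#' Private allele richness per subpopulation
#'
#' Expected number of alleles seen in a subpopulation's g-copy rarefacted
#' sample and unseen in every other subpopulation's independent rarefacted
#' sample, averaged over usable loci.
#'
#' @inheritParams allelic_richness_partition
#' @return Named numeric vector `P_i >= 0`.
#' @export
private_allele_richness <- function(counts,
                                    included = rownames(counts$ref),
                                    g = NULL) {
  allelic_richness_partition(counts, included, g)$P_i
}

#' Leave-one-out marginal contributions to diversity
#'
#' The contribution of each target subpopulation is the signed percent
#' change of the full-metapopulation diversity totals caused by removing
#' it: `cHT_k = 100 (HT_full - HT_without_k) / HT_full`, with `cHS` and
#' `cDG` defined from the same two partitions and divided by `HT_full` so
#' that `cHS + cDG = cHT` exactly; identically for `cAS`, `cDA`, `cAT`
#' over `AT_full`. Positive means removal loses diversity (the
#' subpopulation contributes favorably). The rarefaction size `g` and the
#' usable-locus set are frozen at their full-set values across all
#' leave-one-out evaluations, so every removal is scored on the same panel.
#'
#' @inheritParams gene_diversity_within
#' @param targets Subpopulations to remove one at a time; default all
#'   included except the outgroup.
#' @param outgroup Label of the pool retained in every evaluation and not
#'   a default target, or `NULL`.
#' @param g Rarefaction size; default [choose_rarefaction_size()] on the
#'   full included set.
#' @return An object of class `contribution_table`: a data frame with one
#'   row per target (columns `subpopulation`, `n`, `HS_i`, `AS_i`, `P_i`,
#'   `cHS`, `cDG`, `cHT`, `cAS`, `cDA`, `cAT`, `g`), with the full-set
#'   partitions attached as attributes `gene` and `allelic`.
#' @export
marginal_contributions <- function(counts,
                                   included = rownames(counts$ref),
                                   targets = NULL, outgroup = NULL,
                                   g = NULL) {
  if (!is.null(outgroup) && !outgroup %in% included)
    stop("outgroup must be part of the included set")
  if (is.null(targets)) targets <- setdiff(included, outgroup)
  if (length(included) < 3L)
    stop("leave-one-out contributions need at least 3 subpopulations")
  if (!all(targets %in% included)) stop("targets must be included")
  gene <- gene_diversity_partition(counts, included)
  if (is.null(g)) g <- choose_rarefaction_size(counts, included)
  al <- allelic_richness_partition(counts, included, g)
  HT <- gene$HT; AT <- al$AT
  if (HT <= 0 || AT <= 0)
    warning("degenerate totals (HT or AT is 0): contributions undefined")
  res <- lapply(targets, function(k) {
    keep <- setdiff(included, k)
    idx <- match(keep, included)
    HSr <- mean(gene$HS_i[idx])
    DGr <- mean(gene$D[idx, idx])
    ASr <- mean(al$AS_i[idx])
    DAr <- mean(al$d[idx, idx])
    c(cHS = if (HT > 0) 100 * (gene$HS - HSr) / HT else NA_real_,
      cDG = if (HT > 0) 100 * (gene$DG - DGr) / HT else NA_real_,
      cHT = if (HT > 0) 100 * (gene$HT - (HSr + DGr)) / HT else NA_real_,
      cAS = if (AT > 0) 100 * (al$AS - ASr) / AT else NA_real_,
      cDA = if (AT > 0) 100 * (al$DA - DAr) / AT else NA_real_,
      cAT = if (AT > 0) 100 * (al$AT - (ASr + DAr)) / AT else NA_real_)
  })
  res <- do.call(rbind, res)
  out <- data.frame(subpopulation = targets,
                    n = unname(counts$sizes[targets]),
                    HS_i = unname(gene$HS_i[targets]),
                    AS_i = unname(al$AS_i[targets]),
                    P_i = unname(al$P_i[targets]),
                    res,
                    g = al$g,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, gene = gene, allelic = al,
            class = c("contribution_table", "data.frame"))
}

#' Group-level diversity partition and contributions
#'
#' Pools each group's subpopulations into a single subpopulation (summing
#' allele counts), then recomputes the partitions and leave-one-out
#' contributions over groups, with the outgroup kept as its own pool. This
#' merging is descriptive only: rarefaction over a pooled group is not
#' comparable with the subpopulation-level analysis.
#'
#' @param counts An [count_alleles()] result at subpopulation level.
#' @param subs The [subpop_map()] carrying `group`/`continent` labels.
#' @param group_by Which label set to pool on: `"group"` or `"continent"`.
#'   Subpopulations without a label form their own pools.
#' @param g Rarefaction size at group level; default recomputed from the
#'   pooled counts.
#' @return A list with `contributions` (a [marginal_contributions()] table
#'   over groups, extended with `n_subpops` and `allelic_richness`
#'   columns), and `counts` (the pooled `allele_counts`).
#' @export
group_level_partition <- function(counts, subs,
                                  group_by = c("group", "continent"),
                                  g = NULL) {
  group_by <- match.arg(group_by)
  labels <- subs[[group_by]]
  subpops <- rownames(counts$ref)
  grp <- if (is.null(labels)) stats::setNames(subpops, subpops) else {
    gl <- labels[subpops]
    gl[is.na(gl) | !nzchar(gl)] <- subpops[is.na(gl) | !nzchar(gl)]
    stats::setNames(unname(gl), subpops)
  }
  og <- subs$outgroup
  if (!is.null(og)) grp[og] <- og
  f <- factor(unname(grp[subpops]), levels = unique(unname(grp[subpops])))
  ref <- rowsum(counts$ref, f)
  total <- rowsum(counts$total, f)
  storage.mode(ref) <- "integer"; storage.mode(total) <- "integer"
  sizes <- as.integer(rowsum(matrix(as.numeric(counts$sizes)), f))
  names(sizes) <- levels(f)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 individuals: ",
         paste(levels(f)[sizes < 2L], collapse = ", "))
  pooled <- structure(list(ref = ref, total = total, loci = counts$loci,
                           sizes = sizes),
                      class = "allele_counts")
  contrib <- marginal_contributions(pooled, outgroup = og, g = g)
  n_sub <- as.integer(table(f))
  names(n_sub) <- levels(f)
  contrib$n_subpops <- unname(n_sub[contrib$subpopulation])
  contrib$allelic_richness <- contrib$AS_i + 1
  list(contributions = contrib, counts = pooled)
}
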