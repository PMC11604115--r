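#' Simulate a structured metapopulation (Balding-Nichols model)
#'
#' Ancestral allele frequencies are drawn uniformly on
#' `ancestral_freq_range`; each subpopulation's frequency at each locus is
#' drawn from the Beta distribution with mean `p0` and variance
#' `F p0 (1 - p0)` (the Balding-Nichols form), genotypes are
#' `Binomial(2, p)` and missingness is completely at random. An optional
#' outgroup pool is drawn directly from the ancestral frequencies,
#' emulating a large admixed reference population centred on the
#' metapopulation frequencies.
#'
#' @param n_subpops Number of differentiated subpopulations (>= 2).
#' @param sizes Individuals per subpopulation (recycled to `n_subpops`).
#' @param n_loci Number of biallelic loci.
#' @param F Differentiation parameter in `[0, 1)`; `F = 0` makes every
#'   subpopulation frequency equal to the ancestral frequency.
#' @param ancestral_freq_range Interval within (0, 1) for the ancestral
#'   frequencies (default `c(0.05, 0.95)`).
#' @param missing_rate Probability a genotype is missing (default 0).
#' @param outgroup_size Individuals in the outgroup pool (0 for none).
#' @param seed Mandatory integer seed: same seed, bit-identical output.
#' @return List with `geno` (a [geno_matrix()]), `subs` (a [subpop_map()]
#'   with the outgroup flagged when present) and `truth` (list with the
#'   ancestral frequencies `p0` and the per-subpopulation frequency matrix
#'   `p`).
#' @export
simulate_metapopulation <- function(n_subpops, sizes, n_loci, F = 0.1,
                                    ancestral_freq_range = c(0.05, 0.95),
                                    missing_rate = 0,
                                    outgroup_size = 0L, seed) {
  stopifnot(n_subpops >= 2L, n_loci >= 1L, F >= 0, F < 1,
            missing_rate >= 0, missing_rate < 1,
            length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1)
  if (missing(seed)) stop("a seed is mandatory (no silent nondeterminism)")
  set.seed(as.integer(seed))
  sizes <- rep_len(as.integer(sizes), n_subpops)
  stopifnot(all(sizes >= 1L))
  p0 <- stats::runif(n_loci, ancestral_freq_range[1], ancestral_freq_range[2])
  if (F > 0) {
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    p <- matrix(stats::rbeta(n_subpops * n_loci, rep(a, each = n_subpops),
                             rep(b, each = n_subpops)),
                n_subpops, n_loci)
  } else {
    p <- matrix(rep(p0, each = n_subpops), n_subpops, n_loci)
  }
  labs <- sprintf("pop%02d", seq_len(n_subpops))
  rownames(p) <- labs
  n_total <- sum(sizes) + outgroup_size
  dose <- matrix(NA_integer_, n_total, n_loci)
  row <- 0L
  assign <- character(n_total)
  for (s in seq_len(n_subpops)) {
    idx <- row + seq_len(sizes[s])
    dose[idx, ] <- matrix(stats::rbinom(sizes[s] * n_loci, 2L,
                                        rep(p[s, ], each = sizes[s])),
                          sizes[s], n_loci)
    assign[idx] <- labs[s]
    row <- row + sizes[s]
  }
  og <- NULL
  if (outgroup_size > 0L) {
    idx <- row + seq_len(outgroup_size)
    dose[idx, ] <- matrix(stats::rbinom(outgroup_size * n_loci, 2L,
                                        rep(p0, each = outgroup_size)),
                          outgroup_size, n_loci)
    og <- "outgroup"
    assign[idx] <- og
  }
  if (missing_rate > 0)
    dose[stats::runif(length(dose)) < missing_rate] <- NA_integer_
  ids <- sprintf("ind%05d", seq_len(n_total))
  rownames(dose) <- ids
  gm <- geno_matrix(dose, loci_table(sprintf("snp%05d", seq_len(n_loci))))
  subs <- subpop_map(stats::setNames(assign, ids), outgroup = og)
  list(geno = gm, subs = subs, truth = list(p0 = p0, p = p, F = F))
}

#' Forward Wright-Fisher simulation of one population
#'
#' Discrete generations of `N_true` random-mating diploids (random union of
#' gametes, selfing allowed, so census equals effective size), unlinked
#' loci evolving by binomial gamete sampling, with a final sample drawn
#' without replacement.
#'
#' @param N_true Diploid census (= effective) size.
#' @param n_loci Number of unlinked biallelic loci.
#' @param generations Generations to simulate (>= 1).
#' @param init_freq Initial allele frequency (scalar or per-locus).
#' @param sample_size Individuals sampled at the final generation
#'   (`<= N_true`).
#' @param seed Mandatory integer seed.
#' @return A [geno_matrix()] of the sampled final generation.
#' @export
simulate_wright_fisher <- function(N_true, n_loci, generations = 10L,
                                   init_freq = 0.5, sample_size = N_true,
                                   seed) {
  stopifnot(N_true >= 2L, generations >= 1L, sample_size <= N_true,
            sample_size >= 1L)
  if (missing(seed)) stop("a seed is mandatory (no silent nondeterminism)")
  set.seed(as.integer(seed))
  p <- rep_len(init_freq, n_loci)
  ## found generation 0 with exactly round(2N p) copies per locus, shuffled
  ## among individuals, so realized initial frequencies equal init_freq
  dose <- vapply(seq_len(n_loci), function(l) {
    k <- round(2L * N_true * p[l])
    copies <- sample(c(rep(1L, k), rep(0L, 2L * N_true - k)))
    copies[seq_len(N_true)] + copies[N_true + seq_len(N_true)]
  }, integer(N_true))
  dose <- matrix(dose, N_true, n_loci)
  for (gen in seq_len(generations)) {
    mothers <- sample.int(N_true, N_true, replace = TRUE)
    fathers <- sample.int(N_true, N_true, replace = TRUE)
    g1 <- matrix(stats::rbinom(N_true * n_loci, 1L,
                               dose[mothers, ] / 2), N_true, n_loci)
    g2 <- matrix(stats::rbinom(N_true * n_loci, 1L,
                               dose[fathers, ] / 2), N_true, n_loci)
    dose <- g1 + g2
  }
  take <- sample.int(N_true, sample_size)
  dose <- dose[take, , drop = FALSE]
  rownames(dose) <- sprintf("wf%04d", seq_len(sample_size))
  geno_matrix(dose, loci_table(sprintf("snp%05d", seq_len(n_loci))))
}

#' Plant a subpopulation-private allele
#'
#' Appends one locus whose alternate allele segregates at the given
#' frequency in the target subpopulation and is absent everywhere else
#' (all other individuals homozygous reference). Fixture for private-allele
#' richness and contribution sign checks.
#'
#' @param gm A [geno_matrix()].
#' @param subs A [subpop_map()].
#' @param target Subpopulation carrying the private allele.
#' @param frequency Alternate-allele frequency in the target, in (0, 1].
#' @param seed Mandatory integer seed (genotypes in the target are drawn
#'   `Binomial(2, frequency)`, redrawn once if the allele fails to appear).
#' @return A [geno_matrix()] with one extra locus (`private1` on
#'   chromosome "Z").
#' @export
plant_private_allele <- function(gm, subs, target, frequency, seed) {
  if (frequency <= 0 || frequency > 1) stop("frequency must be in (0, 1]")
  if (!target %in% subs$assignment) stop("unknown target subpopulation")
  if (missing(seed)) stop("a seed is mandatory (no silent nondeterminism)")
  set.seed(as.integer(seed))
  ids <- individual_ids(gm)
  in_target <- subs$assignment[ids] == target
  alt_dose <- rep(0L, length(ids))
  draw <- stats::rbinom(sum(in_target), 2L, frequency)
  if (all(draw == 0L)) draw <- stats::rbinom(sum(in_target), 2L, frequency)
  if (all(draw == 0L)) draw[1] <- 1L
  alt_dose[in_target] <- draw
  new_id <- make.unique(c(gm$loci$id, "private1"))[ncol(gm$dose) + 1L]
  new_loci <- rbind(gm$loci,
                    loci_table(new_id, chromosome = "Z",
                               position = max(gm$loci$position) + 1L))
  dose <- cbind(gm$dose, 2L - alt_dose)
  geno_matrix(dose, new_loci, individual_ids = ids)
}

#' Moment estimator of the differentiation parameter F
#'
#' Weir-Cockerham-style variance-components estimator of FST from
#' genotypes, as the ratio of the summed among-subpopulation components to
#' the summed total variance over loci. Used to calibrate the
#' Balding-Nichols simulator, whose differentiation parameter is the
#' expected FST.
#'
#' @param gm A [geno_matrix()] (complete data assumed; missing genotypes
#'   are dropped per locus and subpopulation).
#' @param subs A [subpop_map()]; the outgroup, if any, is excluded.
#' @return Scalar multi-locus FST estimate.
#' @export
moment_fst <- function(gm, subs) {
  check_assignment(gm, subs)
  labs <- setdiff(subpop_labels(subs), subs$outgroup)
  grp <- factor(subs$assignment[individual_ids(gm)], levels = labs)
  keep <- !is.na(grp)
  X <- gm$dose[keep, , drop = FALSE]
  grp <- grp[keep]
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  n_i <- rowsum(obs + 0, grp)                      # individuals per subpop/locus
  p_i <- rowsum(X0, grp) / (2 * n_i)
  het_i <- rowsum((X == 1L & obs) + 0, grp) / n_i  # observed het proportion
  r <- length(labs)
  nbar <- colMeans(n_i)
  nc <- (r * nbar - colSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * sweep(p_i, 2L, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * het_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

#' Inject a null-allele artifact at a locus
#'
#' Emulates a null (non-amplifying) allele: each heterozygote at the locus
#' is recoded as a homozygote (random side) with probability `beta`,
#' producing the heterozygote deficit that the FIS screen targets.
#'
#' @param gm A [geno_matrix()].
#' @param locus Locus id or column index.
#' @param beta Probability a heterozygote is recoded, in \[0, 1\].
#' @param seed Mandatory integer seed.
#' @return A [geno_matrix()] with the locus degraded.
#' @export
inject_null_allele_locus <- function(gm, locus, beta, seed) {
  stopifnot(beta >= 0, beta <= 1)
  if (missing(seed)) stop("a seed is mandatory (no silent nondeterminism)")
  set.seed(as.integer(seed))
  d <- gm$dose[, locus]
  het <- which(!is.na(d) & d == 1L)
  flip <- het[stats::runif(length(het)) < beta]
  d[flip] <- 2L * stats::rbinom(length(flip), 1L, 0.5)
  gm$dose[, locus] <- d
  gm
}
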