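## Shared fixtures and independent oracles for the test suite.

## allele_counts built directly from a reference-frequency matrix and a
## common per-cell copy number (rounded to realizable integer counts)
counts_from_freq <- function(p, copies = 20L) {
  p <- as.matrix(p)
  ref <- matrix(as.integer(round(p * copies)), nrow(p), ncol(p))
  total <- matrix(as.integer(copies), nrow(p), ncol(p))
  rownames(ref) <- rownames(total) <-
    if (is.null(rownames(p))) paste0("pop", seq_len(nrow(p))) else rownames(p)
  allele_counts(ref, total)
}

## random allele_counts instance: S subpops, L loci, even totals >= 4
random_counts <- function(seed, S = NULL, L = NULL) {
  set.seed(seed)
  if (is.null(S)) S <- sample(3:7, 1)
  if (is.null(L)) L <- sample(5:25, 1)
  total <- matrix(2L * sample(2:30, S * L, replace = TRUE), S, L)
  ref <- matrix(rbinom(S * L, total, runif(S * L)), S, L)
  storage.mode(ref) <- "integer"
  allele_counts(ref, total)
}

## gene diversity of pooled equal-weight frequencies (independent route)
pooled_gene_diversity <- function(counts) {
  p <- allele_freq(counts)
  pool <- colMeans(p)
  mean(1 - pool^2 - (1 - pool)^2)
}

## -- exhaustive-enumeration oracles for the hypergeometric rarefaction --
## A sample configuration is a vector of allele labels (copy list); the
## oracle enumerates every g-subset of the copies by index.

## mean number of distinct alleles over all g-subsets
enum_allele_count <- function(copies, g) {
  labels <- rep(seq_along(copies), copies)
  subs <- utils::combn(length(labels), g)
  mean(apply(subs, 2L, function(ix) length(unique(labels[ix]))))
}

## probability each allele is unseen in a g-subset (enumeration)
enum_unseen <- function(copies, g) {
  labels <- rep(seq_along(copies), copies)
  subs <- utils::combn(length(labels), g)
  vapply(seq_along(copies), function(a)
    mean(apply(subs, 2L, function(ix) !a %in% labels[ix])), numeric(1))
}

## expected alleles present in i's g-sample and absent from j's
enum_absent_count <- function(copies_i, copies_j, g) {
  qi <- enum_unseen(copies_i, g)
  qj <- enum_unseen(copies_j, g)
  sum((1 - qi) * qj)
}

## expected alleles private to subpop i among K subpops (rows of cnt)
enum_private <- function(cnt, i, g) {
  Q <- t(vapply(seq_len(nrow(cnt)), function(s) enum_unseen(cnt[s, ], g),
                numeric(ncol(cnt))))
  sum((1 - Q[i, ]) * apply(Q[-i, , drop = FALSE], 2L, prod))
}

## two-cluster genotype fixture for PCA tests
two_cluster_geno <- function(n_per = 5L, L = 20L) {
  dose <- rbind(matrix(0L, n_per, L), matrix(2L, n_per, L))
  extra <- matrix(rep(c(0L, 1L), each = n_per), ncol = 1)  # avoid constancy
  dose <- cbind(dose, extra, 2L - extra)
  rownames(dose) <- paste0("i", seq_len(2L * n_per))
  geno_matrix(dose, loci_table(paste0("L", seq_len(ncol(dose)))))
}

## full-sib families from distinct parent pairs, parents drawn at fixed p
sim_sib_families <- function(n_fam, fam_size, L, seed,
                             freq_range = c(0.2, 0.8)) {
  set.seed(seed)
  p <- runif(L, freq_range[1], freq_range[2])
  n <- n_fam * fam_size
  dose <- matrix(0L, n, L)
  row <- 0L
  for (f in seq_len(n_fam)) {
    mo <- rbinom(L, 2L, p)
    fa <- rbinom(L, 2L, p)
    for (k in seq_len(fam_size)) {
      row <- row + 1L
      dose[row, ] <- rbinom(L, 1L, mo / 2) + rbinom(L, 1L, fa / 2)
    }
  }
  rownames(dose) <- paste0("sib", seq_len(n))
  geno_matrix(dose, loci_table(paste0("L", seq_len(L))))
}

## unrelated individuals drawn independently at fixed frequencies
sim_unrelated <- function(n, L, seed, freq_range = c(0.2, 0.8)) {
  set.seed(seed)
  p <- runif(L, freq_range[1], freq_range[2])
  dose <- matrix(rbinom(n * L, 2L, rep(p, each = n)), n, L)
  rownames(dose) <- paste0("u", seq_len(n))
  geno_matrix(dose, loci_table(paste0("L", seq_len(L))))
}

## small genotype fixture with named subpopulations
small_metapop <- function(seed = 42L, n_subpops = 4L, size = 8L,
                          n_loci = 30L, F = 0.15, missing_rate = 0,
                          outgroup_size = 0L) {
  simulate_metapopulation(n_subpops, size, n_loci, F = F,
                          missing_rate = missing_rate,
                          outgroup_size = outgroup_size, seed = seed)
}
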