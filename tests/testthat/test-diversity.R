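test_that("within-subpopulation gene diversity matches hand evaluation", {
  cnt <- counts_from_freq(rbind(c(0.5, 0.5), c(0.1, 0.5), c(0, 0)),
                          copies = 10L)
  hs <- gene_diversity_within(cnt)
  expect_equal(unname(hs[1]), 0.5)
  expect_equal(unname(hs[2]), (0.18 + 0.5) / 2)   # p = 0.1 and p = 0.5
  expect_equal(unname(hs[3]), 0)                  # monomorphic
})

test_that("Nei minimum distance matches hand evaluation and is symmetric", {
  cnt <- counts_from_freq(rbind(1, 0, 0.5, 0.1), copies = 10L)
  expect_equal(nei_minimum_distance(cnt, "pop1", "pop2"), 1)
  expect_equal(nei_minimum_distance(cnt, "pop3", "pop4"), 0.16)
  expect_equal(nei_minimum_distance(cnt, "pop1", "pop1"), 0)
  expect_equal(nei_minimum_distance(cnt, "pop4", "pop3"),
               nei_minimum_distance(cnt, "pop3", "pop4"))
})

test_that("gene diversity partition: fixed-difference case and identities", {
  cnt <- counts_from_freq(rbind(1, 0), copies = 10L)
  gp <- gene_diversity_partition(cnt)
  expect_equal(gp$HS, 0)
  expect_equal(gp$DG, 0.5)
  expect_equal(gp$HT, 0.5)
  expect_equal(gp$HT, pooled_gene_diversity(cnt), tolerance = 1e-12)
  ## n identical subpopulations: DG = 0, HT = HS
  cnt2 <- counts_from_freq(matrix(rep(c(0.3, 0.7, 0.5), 4), 4, 3,
                                  byrow = TRUE), copies = 20L)
  gp2 <- gene_diversity_partition(cnt2)
  expect_equal(gp2$DG, 0)
  expect_equal(gp2$HT, gp2$HS)
  expect_error(gene_diversity_partition(cnt, included = "pop1"),
               "at least 2")
})

test_that("HT = HS + DG equals pooled gene diversity on random instances", {
  for (s in 1:50) {
    cnt <- random_counts(s)
    gp <- gene_diversity_partition(cnt)
    expect_equal(gp$HT, gp$HS + gp$DG, tolerance = 1e-12)
    expect_equal(gp$HT, pooled_gene_diversity(cnt), tolerance = 1e-12)
  }
})

test_that("rarefaction size g follows the minimum observed copy count", {
  sim <- simulate_metapopulation(3, sizes = c(6, 10, 50), n_loci = 10,
                                 F = 0.1, seed = 5)
  cnt <- count_alleles(sim$geno, sim$subs)
  expect_identical(choose_rarefaction_size(cnt), 12L)
  ## one missing genotype in the smallest subpopulation at one locus
  gm2 <- sim$geno
  gm2$dose[1, 1] <- NA_integer_
  cnt2 <- count_alleles(gm2, sim$subs)
  expect_identical(choose_rarefaction_size(cnt2), 10L)
  ## explicit override is honoured by the partition
  al <- allelic_richness_partition(cnt, g = 8)
  expect_identical(al$g, 8L)
})

test_that("rarefacted allele count: worked example, bounds, monotonicity", {
  expect_equal(rarefacted_allele_count(c(3, 1), 2), 1.5)
  expect_equal(rarefacted_allele_count(c(3, 1), 4), 2)    # g = N: observed
  expect_equal(rarefacted_allele_count(c(6, 0), 4), 1)    # monomorphic
  expect_error(rarefacted_allele_count(c(3, 1), 5), "exceeds")
  ## non-decreasing in g
  for (g in 3:9)
    expect_gte(rarefacted_allele_count(c(7, 3), g + 1),
               rarefacted_allele_count(c(7, 3), g))
})

test_that("rarefaction equals exhaustive subset enumeration (oracle)", {
  for (N in c(4L, 6L, 9L)) {
    for (ref in 0:N) {
      for (g in seq(2L, N, by = 2L)) {
        expect_equal(rarefacted_allele_count(c(ref, N - ref), g),
                     enum_allele_count(c(ref, N - ref), g),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("absent-allele count matches enumeration and worked example", {
  ## i counts (3,1), j counts (4,0), g = 2
  expect_equal(rarefacted_absent_count(c(3, 1), c(4, 0), 2), 0.5)
  expect_equal(rarefacted_absent_count(c(4, 0), c(3, 1), 2), 0)
  ## fixed for alternative alleles -> 1 in each direction
  expect_equal(rarefacted_absent_count(c(4, 0), c(0, 4), 2), 1)
  ## identical monomorphic -> 0
  expect_equal(rarefacted_absent_count(c(4, 0), c(4, 0), 2), 0)
  for (s in 1:25) {
    set.seed(s)
    Ni <- sample(3:8, 1); Nj <- sample(3:8, 1)
    ci <- c(sample(0:Ni, 1)); ci <- c(ci, Ni - ci)
    cj <- c(sample(0:Nj, 1)); cj <- c(cj, Nj - cj)
    g <- sample(2:min(Ni, Nj), 1)
    expect_equal(rarefacted_absent_count(ci, cj, g),
                 enum_absent_count(ci, cj, g), tolerance = 1e-12)
  }
})

test_that("allelic partition: fixed-difference case and degenerate cases", {
  cnt <- counts_from_freq(rbind(1, 0), copies = 4L)
  al <- allelic_richness_partition(cnt, g = 2)
  expect_equal(al$AS, 0)
  expect_equal(al$DA, 0.5)
  expect_equal(al$AT, 0.5)
  ## identical subpopulations: DA = 0
  cnt2 <- counts_from_freq(matrix(0.5, 3, 2), copies = 10L)
  al2 <- allelic_richness_partition(cnt2)
  expect_equal(al2$DA, 0)
  expect_equal(al2$AT, al2$AS)
  ## all monomorphic for the same allele: AS = DA = AT = 0
  cnt3 <- counts_from_freq(matrix(1, 3, 2), copies = 10L)
  al3 <- allelic_richness_partition(cnt3)
  expect_equal(al3$AT, 0)
})

test_that("private allele richness matches the product-form enumeration", {
  ## allele fixed private to pop1 contributes 1 at that locus
  cnt <- allele_counts(rbind(c(0L), c(4L), c(4L)),
                       matrix(4L, 3, 1))
  expect_equal(unname(private_allele_richness(cnt, g = 2)[1]), 1)
  ## enumeration oracle over small 3-subpopulation configurations
  for (s in 1:15) {
    set.seed(100 + s)
    cfg <- rbind(sample(0:4, 1), sample(0:4, 1), sample(0:4, 1))
    cnt_mat <- cbind(cfg, 4L - cfg)
    counts <- allele_counts(cnt_mat[, 1, drop = FALSE],
                            matrix(4L, 3, 1))
    P <- private_allele_richness(counts, g = 2)
    for (i in 1:3)
      expect_equal(unname(P[i]), enum_private(cnt_mat, i, 2),
                   tolerance = 1e-12)
  }
  ## sharing an allele with a second subpopulation shrinks P, monotonically
  P_counts <- function(n2) {
    cnt <- allele_counts(matrix(c(2L, n2, 0L), 3, 1),
                         matrix(c(4L, 8L, 4L), 3, 1))
    unname(private_allele_richness(cnt, g = 4)[1])
  }
  vals <- vapply(c(0L, 2L, 4L, 6L), P_counts, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("marginal contributions reproduce the three-subpopulation example", {
  cnt <- counts_from_freq(rbind(1, 0, 1), copies = 10L)
  ct <- marginal_contributions(cnt, targets = rownames(cnt$ref))
  expect_equal(ct$cHT[ct$subpopulation == "pop2"], 100)
  expect_equal(ct$cHT[ct$subpopulation == "pop1"], -12.5)
  expect_equal(ct$cHT[ct$subpopulation == "pop3"], -12.5)
})

test_that("contribution additivity and homogeneity hold", {
  for (s in 1:25) {
    cnt <- random_counts(s, S = 5)
    ct <- marginal_contributions(cnt)
    expect_equal(ct$cHS + ct$cDG, ct$cHT, tolerance = 1e-10)
    expect_equal(ct$cAS + ct$cDA, ct$cAT, tolerance = 1e-10)
  }
  ## identical subpopulations: every contribution exactly 0
  cnt0 <- counts_from_freq(matrix(rep(c(0.2, 0.6, 0.5), 4), 4, 3,
                                  byrow = TRUE), copies = 20L)
  ct0 <- marginal_contributions(cnt0)
  expect_true(all(ct0$cHS == 0 & ct0$cDG == 0 & ct0$cHT == 0))
  expect_true(all(abs(ct0$cAS) < 1e-12 & abs(ct0$cAT) < 1e-12))
})

test_that("a private allele drives a positive total allelic contribution", {
  ## pop1 carries the only copies of the alternate allele at locus 2
  p <- rbind(c(0.5, 0.5), c(0.5, 1), c(0.5, 1), c(0.5, 1))
  cnt <- counts_from_freq(p, copies = 20L)
  ct <- marginal_contributions(cnt)
  expect_gt(ct$cAT[ct$subpopulation == "pop1"],
            max(ct$cAT[ct$subpopulation != "pop1"]))
  expect_gt(ct$cAT[ct$subpopulation == "pop1"], 0)
})

test_that("outgroup is retained and never a default target", {
  sim <- small_metapop(seed = 77, n_subpops = 4, outgroup_size = 30)
  cnt <- count_alleles(sim$geno, sim$subs)
  ct <- marginal_contributions(cnt, outgroup = "outgroup")
  expect_false("outgroup" %in% ct$subpopulation)
  expect_identical(nrow(ct), 4L)
  expect_error(marginal_contributions(cnt, included = c("pop01", "pop02"),
                                      outgroup = "outgroup"),
               "included")
})

test_that("partition outputs are invariant to subpopulation relabeling", {
  cnt <- random_counts(9, S = 5)
  perm <- c("pop4", "pop1", "pop5", "pop3", "pop2")
  ct1 <- marginal_contributions(cnt)
  ct2 <- marginal_contributions(cnt, included = perm)
  m <- match(ct1$subpopulation, ct2$subpopulation)
  expect_equal(ct1$cHT, ct2$cHT[m], tolerance = 1e-12)
  expect_equal(ct1$cAT, ct2$cAT[m], tolerance = 1e-12)
})

test_that("rank order of cHT survives removal of an independent block", {
  ## blocks polymorphic on disjoint locus sets: removals commute
  pA <- rbind(c(0.9, 0.1, 0.5, 0.5), c(0.2, 0.7, 0.5, 0.5),
              c(0.5, 0.4, 0.5, 0.5))
  pB <- rbind(c(0.5, 0.5, 0.9, 0.3), c(0.5, 0.5, 0.1, 0.8))
  cnt <- counts_from_freq(rbind(pA, pB), copies = 20L)
  rownames(cnt$ref) <- rownames(cnt$total) <-
    c("a1", "a2", "a3", "b1", "b2")
  names(cnt$sizes) <- c("a1", "a2", "a3", "b1", "b2")
  whole <- marginal_contributions(cnt, targets = c("a1", "a2", "a3"))
  sub <- marginal_contributions(cnt, included = c("a1", "a2", "a3"),
                                targets = c("a1", "a2", "a3"),
                                g = whole$g[1])
  expect_identical(order(whole$cHT), order(sub$cHT))
})

test_that("group-level partition is consistent with subpopulation analysis", {
  sim <- small_metapop(seed = 13, n_subpops = 4, size = 10)
  cnt <- count_alleles(sim$geno, sim$subs)
  ## trivial grouping (each group = one subpopulation) reproduces
  ## marginal_contributions
  subs_triv <- sim$subs
  subs_triv$group <- stats::setNames(subpop_labels(sim$subs),
                                     subpop_labels(sim$subs))
  res <- group_level_partition(cnt, subs_triv, "group")
  ct <- marginal_contributions(cnt)
  m <- match(ct$subpopulation, res$contributions$subpopulation)
  expect_equal(res$contributions$cHT[m], ct$cHT, tolerance = 1e-12)
  expect_equal(res$contributions$cAT[m], ct$cAT, tolerance = 1e-12)
  ## two groups pooling identical subpopulations = two-pool analysis
  p <- rbind(c(0.8, 0.2), c(0.8, 0.2), c(0.3, 0.6), c(0.3, 0.6),
             c(0.5, 0.5))
  cnt2 <- counts_from_freq(p, copies = 20L)
  subs2 <- subpop_map(stats::setNames(
    rep(paste0("pop", 1:5), each = 2),
    paste0("i", 1:10)))
  subs2$group <- c(pop1 = "G1", pop2 = "G1", pop3 = "G2", pop4 = "G2",
                   pop5 = "G3")
  res2 <- group_level_partition(cnt2, subs2, "group")
  pooled <- counts_from_freq(rbind(c(0.8, 0.2), c(0.3, 0.6), c(0.5, 0.5)),
                             copies = 40L)
  rownames(pooled$ref) <- rownames(pooled$total) <- c("G1", "G2", "G3")
  names(pooled$sizes) <- c("G1", "G2", "G3")
  direct <- marginal_contributions(pooled, g = res2$contributions$g[1])
  m2 <- match(direct$subpopulation, res2$contributions$subpopulation)
  expect_equal(res2$contributions$cHT[m2], direct$cHT, tolerance = 1e-12)
  ## schema mirrors the group-level summary table
  expect_true(all(c("n", "cHS", "cDG", "cHT", "cAS", "cDA", "cAT",
                    "n_subpops", "allelic_richness") %in%
                    names(res$contributions)))
})
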