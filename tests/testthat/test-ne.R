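test_that("pairwise_r2 behaves on duplicated, independent and mirrored loci", {
  gm <- sim_unrelated(60, 5, seed = 4)
  gm$dose[, 2] <- gm$dose[, 1]           # duplicate
  gm$dose[, 3] <- 2L - gm$dose[, 1]      # mirror image
  expect_equal(pairwise_r2(gm, 1, 2), 1)
  expect_equal(pairwise_r2(gm, 1, 3), 1) # perfect negative correlation
  ## dose vectors (0,1,2,2) vs (2,1,0,0)
  gm2 <- geno_matrix(cbind(L1 = c(0L, 1L, 2L, 2L), L2 = c(2L, 1L, 0L, 0L)),
                     loci_table(c("L1", "L2")),
                     individual_ids = paste0("i", 1:4))
  expect_equal(pairwise_r2(gm2, "L1", "L2"), 1)
  ## independently simulated loci at large n: r2 ~ 1/n
  big <- sim_unrelated(10000, 2, seed = 9)
  expect_lt(pairwise_r2(big, 1, 2), 0.01)
  ## monomorphic locus -> undefined
  gm$dose[, 4] <- 2L
  expect_true(is.na(pairwise_r2(gm, 1, 4)))
})

test_that("null r2 stays below 0.01 at n = 10,000 across seeded replicates", {
  vals <- vapply(1:100, function(s) {
    gm <- sim_unrelated(10000, 2, seed = 1000 + s)
    pairwise_r2(gm, 1, 2)
  }, numeric(1))
  expect_true(all(vals < 0.01))
})

test_that("ld_prune removes one of a duplicated pair and audits clean", {
  gm <- sim_unrelated(80, 60, seed = 12)
  gm$dose[, 31] <- gm$dose[, 30]          # adjacent duplicate
  panel <- ld_prune(gm, window = 50, step = 10, r2max = 0.2)
  dup <- gm$loci$id[30:31]
  expect_identical(sum(dup %in% panel$retained), 1L)
  ## audit: no retained within-window pair exceeds the threshold
  audit_pruned_panel <- function(gm, panel) {
    idx <- which(gm$loci$id %in% panel$retained)
    worst <- 0
    for (s in seq(1, length(gm$loci$id), by = panel$step)) {
      win <- seq(s, min(s + panel$window - 1, length(gm$loci$id)))
      act <- intersect(win, idx)
      if (length(act) < 2) next
      r2 <- suppressWarnings(cor(gm$dose[, act], use = "pairwise.complete.obs")^2)
      worst <- max(worst, max(r2[upper.tri(r2)], na.rm = TRUE))
    }
    worst
  }
  expect_lte(audit_pruned_panel(gm, panel), 0.2)
  ## independent loci at this sample size: threshold rarely touched
  gm3 <- sim_unrelated(2000, 40, seed = 13)
  panel3 <- ld_prune(gm3)
  expect_identical(length(panel3$removed), 0L)
})

test_that("LD Ne sign rule: no excess r2 means infinite estimate", {
  ## drift signal exactly zero and negative both map to +Inf
  expect_identical(metapopdiv:::ld_ne_from_drift(0, 50), Inf)
  expect_identical(metapopdiv:::ld_ne_from_drift(-0.001, 50), Inf)
  expect_gt(metapopdiv:::ld_ne_from_drift(0.001, 50), 0)
  ## small-signal limit ~ 1/(3 r2drift) in the S >= 30 regime
  expect_equal(metapopdiv:::ld_ne_from_drift(1e-6, 50) * 3e-6, 1,
               tolerance = 0.01)
})

test_that("molecular similarity enumerates the four allele comparisons", {
  gm <- geno_matrix(cbind(L1 = c(2L, 2L, 0L, 1L)),
                    loci_table("L1"), individual_ids = paste0("i", 1:4))
  expect_equal(molecular_similarity(gm, "i1", "i2", "L1"), 1)
  expect_equal(molecular_similarity(gm, "i1", "i3", "L1"), 0)
  expect_equal(molecular_similarity(gm, "i4", "i4", "L1"), 0.5)
})

test_that("coancestry kinship kernel: same-homozygote pair in a variable trio", {
  ## doses (2,2,0): p = 2/3, h = 5/9; pair (1,2): s = 1 -> k = 1
  gm <- geno_matrix(cbind(L1 = c(2L, 2L, 0L), L2 = c(0L, 0L, 2L)),
                    loci_table(c("L1", "L2")),
                    individual_ids = paste0("i", 1:3))
  cs <- metapopdiv:::coancestry_sums(gm$dose)
  k12 <- cs$numer[1, 2] / cs$W[1, 2]
  expect_equal(k12, 1)
})

test_that("unrelated samples give f1 near zero and very large Ne", {
  f1s <- vapply(1:40, function(s)
    ne_coancestry(sim_unrelated(30, 800, seed = 200 + s),
                  jackknife = FALSE)$f1, numeric(1))
  expect_lt(abs(mean(f1s)), 0.005)
  expect_lt(sd(f1s), 0.01)
  ## a typical unrelated draw implies Ne far above the sample size
  est <- ne_coancestry(sim_unrelated(30, 800, seed = 201), jackknife = FALSE)
  expect_true(est$point > 100 || is.infinite(est$point))
})

test_that("sib families yield finite coancestry Ne near the breeder count", {
  pts <- vapply(1:10, function(s)
    ne_coancestry(sim_sib_families(2, 5, 800, seed = s),
                  jackknife = FALSE)$point, numeric(1))
  expect_true(all(is.finite(pts)))
  ## 4 breeding parents: estimates should sit in a sensible band
  expect_true(all(pts > 2 & pts < 10))
  ## and be smaller than for unrelated samples of the same size
  un <- ne_coancestry(sim_unrelated(10, 800, seed = 55), jackknife = FALSE)
  expect_true(all(pts < un$point))
})

test_that("family structure drives both Ne estimates down, coancestry tracks breeders", {
  ## both methods return small finite estimates on family-structured
  ## samples, far below those for unrelated samples of the same size
  res <- vapply(1:10, function(s) {
    gm <- sim_sib_families(3, 6, 600, seed = 400 + s)
    c(m = ne_coancestry(gm, jackknife = FALSE)$point,
      ld = ne_ld(gm, jackknife = FALSE)$point)
  }, numeric(2))
  expect_true(all(is.finite(res)))
  expect_true(all(res < 30))
  ## coancestry point estimate scales with the number of breeding parents
  med_ne <- vapply(c(2L, 5L), function(nf) {
    median(vapply(1:8, function(s)
      ne_coancestry(sim_sib_families(nf, 6, 500, seed = 600 + 13 * s + nf),
                    jackknife = FALSE)$point, numeric(1)))
  }, numeric(1))
  expect_gt(med_ne[2], med_ne[1])
})

test_that("Ne estimators are invariant to locus and individual order", {
  gm <- sim_sib_families(2, 6, 300, seed = 31)
  ids <- rev(individual_ids(gm))
  loci <- sample(gm$loci$id)
  gm_perm <- subset_geno(gm, individuals = ids, loci = sort(loci))
  expect_equal(ne_ld(gm, jackknife = FALSE)$point,
               ne_ld(gm_perm, jackknife = FALSE)$point, tolerance = 1e-9)
  expect_equal(ne_coancestry(gm, jackknife = FALSE)$point,
               ne_coancestry(gm_perm, jackknife = FALSE)$point,
               tolerance = 1e-9)
})

test_that("jackknife machinery: degenerate and straddling cases", {
  ## constant estimator: identical loci make every delete-one-locus
  ## jackknife replicate identical -> zero-width CI at the point
  set.seed(6)
  col <- rbinom(8, 2, 0.5)
  dose <- matrix(rep(col, 10), 8, 10)
  rownames(dose) <- paste0("i", 1:8)
  gm <- geno_matrix(dose, loci_table(paste0("L", 1:10)))
  est <- ne_coancestry(gm, jackknife = TRUE)
  expect_equal(est$ci_low, est$point, tolerance = 1e-9)
  expect_equal(est$ci_high, est$point, tolerance = 1e-9)
  ## f1 jackknife distribution straddling zero -> infinite upper bound
  un <- ne_coancestry(sim_unrelated(15, 200, seed = 77), jackknife = TRUE)
  expect_identical(un$ci_high, Inf)
  ## jackknife_ci wrapper returns the same bounds as the estimator
  gm2 <- sim_sib_families(2, 5, 200, seed = 78)
  est2 <- ne_coancestry(gm2, jackknife = TRUE)
  expect_equal(unname(jackknife_ci(gm2, "coancestry")),
               c(est2$ci_low, est2$ci_high))
})

test_that("Wright-Fisher recovery: LD Ne tracks truth and its ordering", {
  meds <- vapply(c(50, 200), function(ne_true) {
    pts <- vapply(1:8, function(s) {
      gm <- simulate_wright_fisher(ne_true, 800, generations = 10,
                                   seed = ne_true * 1000 + s)
      ne_ld(gm, jackknife = FALSE)$point
    }, numeric(1))
    median(pts)
  }, numeric(1))
  expect_lt(abs(meds[1] - 50) / 50, 0.35)
  expect_gt(meds[2], meds[1])   # larger true Ne -> larger estimate
})

test_that("ne_table reports both methods per subpopulation", {
  sim <- small_metapop(seed = 19, n_subpops = 3, size = 12, n_loci = 120,
                       F = 0.05)
  tab <- ne_table(sim$geno, sim$subs, jackknife = FALSE)
  expect_identical(sort(unique(tab$method)), c("LD", "coancestry"))
  expect_identical(length(unique(tab$subpopulation)), 3L)
  expect_true(all(tab$point > 0))
})
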