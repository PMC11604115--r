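# metapopdiv

Which subpopulations of a structured, SNP-genotyped metapopulation act as
**reservoirs of genetic diversity** for the species as a whole? This package
answers that question for conservation geneticists and genebank managers
working with panels of local breeds or demes: it partitions two
complementary diversity measures into within- and between-subpopulation
components, scores every subpopulation by the *leave-one-out* change in
each component while a designated outgroup (e.g. a pooled set of
cosmopolitan commercial breeds) is always retained, and cross-checks the
results against per-subpopulation effective population size estimated from
the same genotypes.

## The statistics at its core

With equal subpopulation weights and plug-in allele frequencies
`p_il`:

* **Gene diversity**: `HS_i = mean_l (1 − Σ_a p_ila²)`,
  Nei's minimum distance `D_ij = mean_l ½ Σ_a (p_ila − p_jla)²`, and

  `HT = HS + DG`,  with `HS = mean_i HS_i`, `DG = mean over all n² ordered pairs of D_ij`.

  Under these conventions `HT` equals the gene diversity of the pooled
  equal-weight frequencies — an identity the test suite verifies to 1e-12.
* **Allelic richness**, rarefacted to `g` gene copies by hypergeometric
  sampling: `AT = AS + DA`, where `AS` counts expected segregating alleles
  within subpopulations (minus one) and `DA` counts expected alleles
  present in one subpopulation's `g`-copy sample and absent from
  another's. Private-allele richness `P_i` uses the same machinery.
* **Marginal contributions**: for each target `k`,
  `cHT_k = 100 (HT_full − HT_−k)/HT_full` (likewise `cAT_k`), with the
  component contributions divided by the same total so that
  `cHS + cDG = cHT` and `cAS + cDA = cAT` exactly. Positive = removal
  loses diversity = favorable contributor.
* **Effective size**: LD method (Burrows composite r², published
  random-mating bias corrections, Pcrit screen, windowed LD pruning) and
  molecular-coancestry method (identity-in-state kinship, loci weighted by
  `1 − expected homozygosity`, rescaled to an absolute coancestry base);
  95% jackknife intervals on the drift-signal scale, so intervals crossing
  zero report an infinite upper bound.
* **Downstream statistics**: genotype PCA with per-subpopulation mean
  eigenvectors, contribution-sign × sample-size classification, a
  generalized R×C Cochran–Mantel–Haenszel test, Pearson/Spearman
  correlations with pairwise exclusion of infinite estimates.

Input is PLINK text PED/MAP; seeded Balding–Nichols and Wright–Fisher
simulators make every stage testable without any external data.

## Worked example

```r
library(metapopdiv)

sim <- simulate_metapopulation(5, sizes = c(10, 14, 8, 20, 12),
                               n_loci = 400, F = 0.15,
                               outgroup_size = 60, seed = 2024)
cnt <- count_alleles(sim$geno, sim$subs)
gene_diversity_partition(cnt)
#> <gene diversity partition> 6 subpopulations
#>   HS = 0.300042  DG = 0.046842  HT = 0.346884
allelic_richness_partition(cnt)
#> <allelic richness partition> 6 subpopulations, g = 16
#>   AS = 0.835718  DA = 0.092973  AT = 0.928691

ct <- marginal_contributions(cnt, outgroup = "outgroup")
ct[, c("subpopulation", "n", "cHS", "cDG", "cHT", "cAS", "cDA", "cAT")]
#>   subpopulation  n    cHS   cDG    cHT    cAS   cDA       cAT
#> 1         pop01 10 -0.462 1.321  0.859 -0.310 0.314  0.003994
#> 2         pop02 14 -0.666 1.125  0.458 -0.344 0.343 -0.000511
#> 3         pop03  8 -1.728 0.923 -0.804 -1.146 1.048 -0.097694
#> 4         pop04 20  0.309 0.658  0.968  0.148 0.521  0.668941
#> 5         pop05 12 -0.315 1.144  0.829 -0.436 0.491  0.055314
```

Reading the table: of the metapopulation's total gene diversity, removing
`pop04` would lose 0.97% (`cHT`), and it is also the strongest allelic
reservoir (`cAT = 0.67%`); `pop03` is the one unfavorable contributor on
both measures (it is small and holds no distinct alleles). Each row's
within and between components sum to its total by construction.

Effective size from a drift simulation with known truth `Ne = 50`:

```r
gm <- simulate_wright_fisher(50, 2000, generations = 10, seed = 7)
ne_ld(gm)
#> <ne_estimate LD> point = 47.3  95% CI [34.8, 72.3]  (loci = 1998)
```

The end-to-end pipeline (filters → partitions → contributions for the
whole set and configured subsets → pruning → Ne → PCA → association
statistics, all as TSV plus a JSON manifest):

```r
cfg <- analysis_config(outgroup = "outgroup", seed = 1)
run_full_analysis(sim$geno, sim$subs, cfg, out_dir = "results/run1")
```

A thin command-line wrapper with subcommands (`simulate`, `filter`,
`diversity`, `contributions`, `ne`, `pca`, `stats`, `all`) is installed at
`system.file("cli/metapopdiv-cli.R", package = "metapopdiv")`.

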