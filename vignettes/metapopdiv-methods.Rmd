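---
title: "Methods: partitioning metapopulation diversity and estimating effective size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning metapopulation diversity and estimating effective size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapopdiv)
```

## The question the package answers

Given biallelic SNP genotypes for many individuals assigned to named
subpopulations (breeds, demes, sampling sites), which subpopulations act as
*reservoirs* of genetic diversity for the metapopulation as a whole? The
package answers this by decomposing two complementary diversity measures
into within- and between-subpopulation components and asking, for each
subpopulation in turn, how much of each component is lost when that
subpopulation is removed while a designated outgroup (for example a pooled
set of cosmopolitan commercial breeds) is always retained as a reference.

Gene diversity rewards balanced allele frequencies; allelic richness
rewards carrying alleles that other subpopulations lack. A subpopulation can
contribute favorably to one and unfavorably to the other, which is exactly
why both are computed.

## Gene-diversity partition

For subpopulation $i$ with reference-allele frequency $p_{il}$ at locus
$l$, the within-subpopulation gene diversity (expected heterozygosity) is

$$HS_i = \frac{1}{L}\sum_l \left(1 - \sum_a p_{ila}^2\right),$$

averaged over the loci usable in that subpopulation (at least one observed
gene copy). Between subpopulations, Nei's minimum genetic distance is

$$D_{ij} = \frac{1}{L}\sum_l \tfrac12 \sum_a (p_{ila} - p_{jla})^2 ,$$

and the partition is $HS = \frac1n\sum_i HS_i$,
$DG = \frac1{n^2}\sum_{i}\sum_{j} D_{ij}$ (all $n^2$ ordered pairs,
self-pairs contributing zero), and $HT = HS + DG$.

Two design choices deserve comment, both made where the framework leaves
the implementer latitude:

* **Equal subpopulation weights.** $HS$, $DG$, $AS$ and $DA$ weight every
  subpopulation equally regardless of sample size. This makes $HT$ equal,
  exactly, to the gene diversity of the equal-weight pooled frequency
  vector — an identity the test suite verifies to $10^{-12}$ on random
  instances, and a useful invariant because it gives the decomposition an
  independent, single-formula cross-check.
* **Averaging over $n^2$ ordered pairs** (rather than $n(n-1)$ distinct
  pairs). Only the $n^2$ convention yields the pooled-frequency identity
  above; the distinct-pair average inflates $DG$ by $n/(n-1)$ and breaks
  it.

Frequencies are plug-in estimates $\hat p = x/2m$ over observed copies
only; no small-sample ($2n/(2n-1)$) correction is applied anywhere in the
partition, so the decomposition identities hold exactly rather than
approximately.

## Allelic-richness partition

Raw allele counts are incomparable across unequal samples, so all counts
are *rarefacted* to a common number of gene copies $g$: the expected number
of distinct alleles among $g$ copies drawn without replacement from the
$N$ observed copies of a subpopulation-locus, of which $N_a$ carry allele
$a$, is

$$r(g) = \sum_a \left[1 - \binom{N - N_a}{g}\Big/\binom{N}{g}\right].$$

$AS_i$ is the per-subpopulation mean of $r(g) - 1$ (the number of
*segregating* alleles beyond the first), $AS$ its equal-weight mean. The
between component uses the expected number of alleles present in a
$g$-copy sample from $i$ and absent from an independent $g$-copy sample
from $j$,

$$d_{ij} = \sum_a (1 - Q_{ia})\, Q_{ja}, \qquad
  Q_{xa} = \binom{N_x - N_{xa}}{g}\Big/\binom{N_x}{g},$$

symmetrized per pair, and $DA$ is again the $n^2$ ordered-pair mean with a
zero diagonal, giving $AT = AS + DA$. Private-allele richness per
subpopulation is $P_i = \sum_a (1 - Q_{ia}) \prod_{j \ne i} Q_{ja}$,
averaged over loci.

All three quantities are evaluated through `lchoose` in log space, so they
are exact to machine precision; the test suite checks them against
brute-force enumeration of every $g$-subset for all small configurations
($N \le 12$).

**Choice of $g$.** By default $g$ is the minimum observed `copies_total`
over the included subpopulation-locus cells (so every cell can be
rarefacted), and it is *frozen* across all leave-one-out re-evaluations:
removing a subpopulation may raise the admissible minimum, but letting $g$
float would change the richness scale between the full and reduced
metapopulations and make $AT$ values incomparable. The usable-locus set is
frozen for the same reason. A fixed override (`g = ...`) is available.

## Leave-one-out contributions

For each target subpopulation $k$ the partitions are recomputed on the
included set minus $k$ (outgroup always retained) and reported as signed
percentages of the full-set total:

$$cHT_k = 100\,\frac{HT_{\text{full}} - HT_{-k}}{HT_{\text{full}}},\qquad
  cHS_k = 100\,\frac{HS_{\text{full}} - HS_{-k}}{HT_{\text{full}}},$$

and similarly for $cDG$, and for $cAS$, $cDA$, $cAT$ over
$AT_{\text{full}}$. Dividing the component changes by the *total* ($HT$ or
$AT$) rather than by each component's own value is deliberate: it is the
only convention under which $cHS + cDG = cHT$ and $cAS + cDA = cAT$ hold
exactly, which the suite asserts to $10^{-10}$. Positive means removal
loses diversity — the subpopulation contributes favorably. When
$HT_{\text{full}} = 0$ or $AT_{\text{full}} = 0$ the contributions are
reported as undefined rather than zero.

A worked single-locus example with three subpopulations at frequencies
$(1, 0, 1)$: the full partition gives $HT = 4/9$; removing the divergent
$p = 0$ subpopulation collapses $HT$ to $0$ ($cHT = +100\%$), removing
either fixed subpopulation gives $HT = 1/2$ ($cHT = -12.5\%$).

Group-level tables (pooling subpopulations by geographic area before the
leave-one-out loop) are supported but explicitly descriptive: pooling
changes the rarefaction base and the metapopulation frequency spectrum, so
group results are not comparable with the subpopulation-level analysis.

## Effective population size

Two single-sample estimators are provided so that contribution estimates
can be checked against demographic signal.

**LD method.** Linkage disequilibrium between unlinked loci in a closed
random-mating population reflects drift: $E[r^2_{\text{drift}}] \approx
1/(3N_e)$. For unphased genotypes the package measures the Burrows
composite correlation
$\hat\Delta = \frac{S}{S-1}\left(\overline{x y}/2 - 2\hat p_A \hat
p_B\right)$, $\hat r^2 = \hat\Delta^2 / (\hat p_A \hat q_A \hat p_B \hat
q_B)$, averaged over all pairs of retained loci. The sampling expectation
subtracted from $\hat r^2$, and the quadratic inversion from the excess to
$\hat N_e$, use the published random-mating constants for the $S \ge 30$
and $S < 30$ regimes, isolated in one block of `R/ne.R` (Waples 2006
Conserv Genet 7:167; Waples & Do 2008 Mol Ecol Resour 8:753). The Burrows
form matters: the plain Pearson dose correlation has null expectation
$\approx 1/(S-1)$, not the $1/S + 3.19/S^2$ those constants assume, and
using it inflates $\hat N_e$ by 25–55% in Wright–Fisher recovery runs.
Loci with minor-allele frequency below `pcrit` (default 0.05) are screened
out; a drift signal $\le 0$ reports $N_e = \infty$; the panel is first
thinned by windowed LD pruning (default 50-SNP windows, step 10,
$r^2 \le 0.2$).

**Molecular-coancestry method.** At locus $l$ the identity-in-state of two
diploids with doses $x_i, x_j$ is $s = [x_i x_j + (2-x_i)(2-x_j)]/4$; the
unrelated-pair expectation is the expected homozygosity $h_l = \sum_a
\hat p_a^2$, and the per-pair kinship $(s_l - h_l)/(1 - h_l)$ is combined
over loci with weights $w_l = 1 - h_l$, up-weighting loci with balanced
frequencies where identity in state is most informative. Because $h_l$ is
computed from the sample's own frequencies, the mean relative kinship over
distinct pairs is forced to about $-1/(2n-1)$ *whatever the true
relatedness* — the signal is absorbed into the reference. The estimator
therefore rescales to an absolute base in which a non-inbred individual's
self-coancestry is $1/2$: with $m_s$ the mean self-kinship and $m_p$ the
mean pair kinship on the relative scale, the base mean coancestry is
$\bar g = (1/2 - m_s)/(1 - m_s)$ and $f_1 = m_p(1-\bar g) + \bar g$, with
$\hat N_e = 1/(2 f_1)$. On simulated full-sib families this recovers
approximately the number of breeding parents, and on unrelated samples
$f_1 \approx 0$ (infinite $N_e$), which is the behavior the method is
meant to have. Note the two estimators answer subtly different questions —
the coancestry method sees the effective number of breeders behind the
sampled cohort and is typically the smaller, more stable number when
strong family structure is present; on our family-structured simulations
it is *not* systematically below the LD estimate, because the LD estimate
itself is biased downward by family mixture LD.

**Confidence intervals** are 95% jackknife intervals built on the
drift-signal scale ($r^2_{\text{drift}}$ or $f_1$) and then transformed,
so an interval crossing zero maps to an infinite upper bound — deleting
one individual for the LD method, one locus for the coancestry method.

## Downstream statistics

Genotype PCA centres doses by $2\hat p$ and scales by
$\sqrt{2\hat p(1-\hat p)}$; missing doses are mean-imputed *for the PCA
only* (the diversity modules never see imputed values); component signs
are fixed by making each component's largest-magnitude entry positive.
Per-subpopulation mean eigenvectors summarize structure.

Subpopulations are cross-classified by the signs of $cHT$ and $cAT$ and by
sample-size class, and the association is tested with the generalized
R×C Cochran–Mantel–Haenszel statistic. The statistic is implemented
directly (multivariate hypergeometric covariance in Kronecker form)
because the stats-package implementation rejects single-stratum arrays;
for multi-stratum inputs the two agree to $10^{-10}$ and that agreement is
itself a test. Spearman correlations are Pearson on mid-ranks; pairs with
non-finite values (infinite $N_e$) are dropped with the count reported.

## The synthetic-data generators

`simulate_metapopulation()` draws ancestral frequencies uniformly on
$(0.05, 0.95)$ and subpopulation frequencies from the Balding–Nichols Beta
distribution with mean $p_0$ and variance $F p_0 (1 - p_0)$; genotypes are
binomial, missingness is completely at random, and the optional outgroup
is drawn directly from the ancestral frequencies, emulating a large
admixed reference pool centred on the metapopulation. The differentiation
parameter is the expected $F_{ST}$, and a Weir–Cockerham-style moment
estimator (`moment_fst`) recovers $F = 0.2$ to within $\pm 0.005$ over
5,000 loci — well inside the $\pm 0.03$ the calibration checks demand.

`simulate_wright_fisher()` is the validation harness for the $N_e$
estimators: discrete generations, random union of gametes with selfing
allowed (so census equals effective size exactly), unlinked loci. The
founding generation carries exactly `init_freq` (gene copies dealt out and
shuffled), so the one-generation drift variance $p(1-p)/(2N)$ is testable
without founding noise. Recovery runs use 2,000 loci, 10 generations
(unlinked-locus LD equilibrates within a handful of generations since
mixture LD decays by 75% per generation), samples of $S = N_e \in \{25,
50, 100\}$, and 30 replicates per setting — sizes chosen so the whole
harness runs in about a minute while leaving the median estimator's
sampling error well below the 20% band being checked.

What the generators deliberately do **not** emulate: linkage (all loci
independent, so LD-pruning behavior on real dense maps is exercised only
via constructed correlated blocks), ascertainment bias of SNP arrays,
genotyping-platform batch effects, selection and migration. Passing tests
therefore certify the estimators under their own model assumptions, not
robustness to array ascertainment — the major caveat attached to
cross-continental comparisons of real data.

`plant_private_allele()` and `inject_null_allele_locus()` are small
fixtures: the first appends a locus private to one subpopulation (its
marginal $cAT$ must strictly increase — a paired, seeded sign check), the
second converts heterozygotes to homozygotes with probability $\beta$,
reproducing the heterozygote-deficit signature that the $F_{IS} > 0.9$
null-allele screen removes.

## Cohort-assembly filters

Subpopulations with fewer than 6 individuals are dropped (rarefaction and
$N_e$ estimates below that size are not meaningful); the outgroup can be
exempted. The null-allele screen removes a locus when its plug-in
$F_{IS} = 1 - H_o/H_e$ exceeds 0.9 in *any* assessed subpopulation —
the screen is evaluated per subpopulation (pooled evaluation would
confound heterozygote deficit with the Wahlund effect), and an include
list restricts it to the genotyping batches that need it. Monomorphic
loci have undefined $F_{IS}$ and are never removed by the screen.

## Numerical and convention choices

* Reference allele on PED input: first allele observed in file order
  (deterministic); every statistic is invariant to the choice, and an
  optional `ref_alleles` argument restores exact dose-level round trips.
* MAP positions are 1-based and carried through untouched.
* Monomorphic loci are retained in the partitions (they contribute
  consistent 0/1 terms); degenerate totals report undefined contributions.
* Rarefaction quantities use `lchoose`; ties in LD pruning resolve by
  file order (the later-indexed locus of an offending pair is dropped).
* All generators require an explicit seed; identical seeds give
  bit-identical output.

## Known limitations

* Only biallelic loci are supported end to end; the rarefaction algebra
  is written per-allele and would extend to microsatellites, but no
  multi-allelic I/O is built.
* The coancestry $N_e$ rests on the self-coancestry anchor
  $f_{\text{self}} = 1/2$, i.e. non-inbred sampled individuals; strongly
  inbred cohorts shift the base and the estimate with it.
* The LD method's bias corrections assume random mating and a closed
  population; admixed or age-structured samples violate both.
* Group-level (pooled) results are descriptive only.
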