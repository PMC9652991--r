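---
title: "Methods: SNP quality control, population structure, and joint-AFS demographic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP quality control, population structure, and joint-AFS demographic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpdemog)
```

`snpdemog` implements a complete population-genomic workflow for
reduced-representation (DArT-style) SNP data in structured, hybridizing
populations: quality control, diversity and differentiation statistics,
outlier scanning, admixture and hybrid-category inference, and
two-population demographic inference from the folded joint allele frequency
spectrum (AFS).  This vignette explains the models and algorithms, the
parameters that matter, the numerical choices, and what the simulation-based
tests do and do not demonstrate about real data.

## Data model

Genotypes are diploid biallelic calls stored as alternate-allele counts
(0/1/2, missing `-9`), with one population label per individual
(`genotype_matrix()`).  Which of a locus' two alleles is called "alternate"
is arbitrary: every statistic in the package is invariant to allele
re-orientation (folding the AFS makes this true by construction on the
demographic side), and the test suite asserts this invariance explicitly.
STRUCTURE (both common dialects, auto-detected), DArT two-row CSV, GT-only
VCF, and aligned FASTA are supported for interchange.

## Quality control

`apply_filters()` applies a fixed-order chain with per-step attrition
reporting: monomorphic removal; locus call rate below 90%; individual call
rate below 80%; mean sequencing depth below 5; technical repeatability below
95%; one SNP per sequenced tag (keeping the highest-call-rate SNP,
ties resolved by position in tag); paralog removal at normalized
tag-sequence Hamming distance at or below 0.25 (the lower-call-rate member
of each too-similar pair is dropped, most-similar pairs first); a
Hardy-Weinberg conditional exact test within *each* population, removing a
locus when p < 1e-5 in any of them; sliding-window LD pruning at genotypic
r² > 0.80 (window 50 loci, step 5, worst pair first, lower call rate
dropped); loci with more than 10% missing data; and minor allele frequency
below 2%.  All inequalities are strict, exactly as the thresholds are
conventionally quoted.

Two choices here were genuinely open.  The step *order* changes attrition
counts, so it is pinned to the order above and reported per step.  The HWE
test is run per population rather than pooled: a pooled test confounds
genotyping error with the Wahlund effect, which in an admixed system is a
biological signal, not an artifact; removing a locus that fails in any
single population is the conservative reading.  The HWE exact test itself is
the conditional test on heterozygote counts given allele counts, summing the
probabilities of all outcomes no more probable than the observed one; it is
verified against full enumeration for every table size used.

## Diversity and differentiation

Per population, `diversity_table()` reports observed heterozygosity,
unbiased expected heterozygosity `2p(1-p)·2n/(2n-1)`, the inbreeding
coefficient `FIS = 1 - sum(Ho_l)/sum(He_l)` (ratio of sums across loci,
unbiased He), mean multilocus heterozygosity, standardized multilocus
heterozygosity (each individual's heterozygous fraction over its typed loci
divided by the mean heterozygosity of those same loci, so the population
mean is ~1 under homogeneous missingness), and allelic richness rarefied to
a common gene-copy count g (default twice the smallest population size) via
the exact hypergeometric form `sum_a [1 - C(N - N_a, g)/C(N, g)]`.

Differentiation uses the Weir & Cockerham (1984) variance-component
estimator theta, combined across loci as a ratio of averages, with
permutation p-values obtained by shuffling individuals between the pair of
populations.  AMOVA follows the Excoffier sum-of-squares decomposition of
squared allele-count differences at three levels — among populations, among
individuals within populations, and within individuals (the heterozygosity
level).  Keeping the within-individual level matters: a two-level
decomposition of diploid genotype distances reports approximately
`2F/(1+F)` instead of `F` and cannot agree with the Weir-Cockerham scale.
The fixation index is the among-population fraction of total molecular
variance.  PhiST applies
the same decomposition to pairwise nucleotide differences between aligned
haplotypes.  AMOVA's index and multilocus theta agree within ±0.02 on
balanced two-population data, which the suite checks.  Permutations default
to 999 with a recorded seed.

## Outlier scanning

`fdist_null()` simulates the neutral joint distribution of (He, FST) under a
hierarchical island model (default 2 groups × 5 demes; the group/deme
structure used by the original FDIST implementations is rarely reported, so
it is exposed in the interface) with the sampled populations spread across
groups.  A single multiplier on the migration matrix is calibrated by
bisection until the realized multilocus FST matches the observed one to
±0.005.  `outlier_scan()` then computes, for each observed locus, a
two-sided empirical tail probability of its FST conditional on its
heterozygosity — null loci are binned by He (width 0.05) with adjacent-bin
pooling until at least 50 null points are available, replacing kernel
smoothing with something simpler and directly testable — followed by
Benjamini-Hochberg correction at FDR 0.05.  Beyond the null's 95% quantile
the tail probability switches from the empirical proportion to an
exponential fit of the exceedances: finite simulation tables floor empirical
p-values at roughly one over the table size, which would make even a
drastically divergent single locus undetectable after multiple-testing
correction; smoothing the extreme tail (in the spirit of generalized-Pareto
smoothing of permutation p-values) removes the floor while agreeing with the
empirical estimate inside the support.  Production null tables use 1e5
simulated loci (the tests use 1e4 to stay fast; the conditional quantiles
stabilize well before that).

## Admixture and hybrid categories

`admixture_fit()` maximizes the standard binomial admixture likelihood
(genotype g_il ~ Binomial(2, sum_k q_ik f_kl)) by expectation-maximization
with multiple random restarts.  EM replaces the block-relaxation ascent of
the reference implementation: the optimum is the same and monotone
likelihood ascent is asserted at every iteration.  `choose_k()` selects K by
masked-genotype cross-validation: a fraction of non-missing entries is
hidden, the model refitted, and predictive cross-entropy scored on the
hidden entries, averaged over replicate folds (default 10).

`hybrid_classify()` is a Gibbs sampler over the six two-generation hybrid
categories — pure parentals P0/P1, F1, F2, and the two backcrosses — each
defined by fixed expected proportions of locus-wise ancestry pairs
(`hybrid_categories()`).  Conditional on an individual's category, its
genotype likelihood at a locus mixes the two parental Hardy-Weinberg laws
and the between-pool law; conditional on category assignments and latent
allele origins, the two parental allele-frequency vectors are updated from
Jeffreys Beta(1/2, 1/2) posteriors.  Classification is typically run on the
300 loci with the highest pairwise Weir-Cockerham theta between the
designated parental populations (`top_fst_loci()`).  Labels are anchored by
initializing the frequency vectors from the sampled parental populations;
known pure individuals can be pinned with the `known` argument (off by
default).  Defaults are 3 chains × 20000 sweeps (5000 burn-in, thin 10);
the category posteriors are Rao-Blackwellized averages of the per-sweep
assignment probabilities, and a between-chain SD above 0.1 for any
individual raises a mixing flag rather than failing silently.

## The joint AFS and its likelihood

`afs_from_matrix()` builds the two-population spectrum at a fixed projection
(n1, n2 gene copies; default 20, 20): each locus contributes its
hypergeometric-expected projected entry mass computed from the non-missing
allele counts, which absorbs missing data; loci with fewer available copies
than the projection are dropped and counted.  The spectrum is folded onto
minor-allele orientation (mirrored cells masked, totals conserved) and the
fixed corners are always masked.

The model spectrum is compared to data by the Poisson composite likelihood
over unmasked cells, with the overall scale theta profiled analytically
(`theta_hat = sum(data)/sum(model)`), the convention of diffusion-based
joint-AFS inference.

## The demographic model family

All models start from an ancestral population of size N_ref that splits at
time `T1` (backwards, in units of 2·N_ref generations) into populations of
relative sizes `nu1`, `nu2`; a nested event time `T2 < T1` optionally
changes sizes to `nu1b`, `nu2b` and/or switches asymmetric migration on or
off (`model_spec()` lists the seven variants: split-only, isolation,
continuous asymmetric migration, secondary contact, secondary contact with
size change, early migration then isolation with size change, and isolation
with size change).  Migration `m12` is the population-scaled rate
2·N_ref·m of gene flow into population 1 from population 2, forward in
time.  `to_biological_units()` converts fitted scaled parameters to
absolute quantities given a mutation rate (default 8e-8 per site per
generation, the conventional rate for DArT-style SNPs in these crustaceans),
a generation time and an effective assayed length; the inverse
transformation is provided for checking.

### Monte-Carlo expected spectra

`expected_afs()` computes the expected spectrum by structured-coalescent
Monte Carlo (Rcpp): genealogies of the sampled copies are simulated under
the epoch structure, and every branch adds its length to the cell indexed by
its descendant counts in the two populations.  This matches the classical
closed forms where they exist (the constant-size spectrum is proportional to
1/i; a vanishing split time recovers the panmictic spectrum; both are
asserted in the tests).  The per-locus data simulator
(`simulate_genotypes()`) shares the same event engine but draws each locus'
genealogy with probability proportional to its total branch length — the
correct conditioning for a locus ascertained to carry a segregating
mutation — via capped rejection sampling, then places one mutation uniformly
on the tree (infinite-sites thinning).  The two readouts cross-validate on
every model of the family in the test suite.  Without the length-weighted
conditioning the simulated data systematically under-represent deep
genealogies and split-time refits are biased low; this is easy to miss and
worth stating plainly.

### Fitting

`fit_model()` maximizes the composite likelihood in log-parameter space,
with `T1` reparameterized as `T2 + dT` so epoch ordering always holds, and
the Monte-Carlo engine seed held fixed within each replicate level (common
random numbers), which makes the surface smooth along one-dimensional rays.
Two properties of this surface dictated the search design, both measured
during development:

* **Cheap surfaces are biased between basins.**  At a few thousand
  genealogies per evaluation, model spectra have empty cells wherever the
  expected mass is small; a floored empty cell containing observed SNPs
  costs tens of log-likelihood units, and models that spread mass over many
  small cells (deep splits) are penalized far more than concentrated ones.
  Model cells are therefore floored at the Monte-Carlo resolution limit
  (a quarter of one average genealogy's contribution, `0.25·sum(m)/R`)
  rather than at machine epsilon, and any decision *between* likelihood
  basins is deferred to a 50000-genealogy surface averaged over two engine
  seeds.

* **Multimodality lives on the split-duration axis and in the migration
  direction.**  Secondary-contact models admit a short-split optimum (recent
  divergence, strong migration) that free search finds easily, deep-split
  optima that plain multistart Nelder-Mead essentially never reaches, and
  distinct gene-flow-direction modes.  Fitted "shape" parameters (sizes,
  rates, event time) transfer usefully between modes, but a shape that only
  pays off after its event times adjust can look terrible on a single
  evaluation.  The optimizer therefore (1) screens random log-uniform starts
  and refines the best by Nelder-Mead, keeping the two most distinct optima
  and a migration-swapped variant; (2) improves the incumbents by
  log-normally perturbed restarts; (3) seeds deep-split candidates from hop
  grids over event time, migration rates and coarse population-size anchors;
  (4) profiles the split duration globally, refining each fixed duration
  conditionally from the two most distinct transplanted pool shapes; and
  (5) re-refines the best profile point of each duration region on a
  larger-replicate plain surface before choosing the argmax and locally
  re-profiling the split time there.

* **The split time of a deep-split secondary-contact history is
  set-identified more than point-identified at these data sizes.**  On
  spectra of 2000 segregating loci at projection (20, 20), the profile
  composite log-likelihood over the split time is typically flat to within
  1-3 units across a several-fold range (the divergence signal rides on the
  product of the split time with the fraction of lineages escaping the
  contact-epoch migration, and the factors are only weakly separated), so
  the argmax wanders across that range between replicate datasets and even
  between optimizer seeds.  Replicate fits with the median reported are the
  honest point summary, and the profile trace printed by
  `fit_model(verbose = TRUE)` shows the flat set explicitly.

`model_select()` ranks fits by AIC (`2k - 2 loglik`, with the profiled
theta counted in k), reporting delta-AIC and Akaike weights; visual
comparison of data and model spectra remains the recommended final check.

### ABC cross-check

`abc_model_choice()` provides an independent, likelihood-free check on model
choice: candidate scenarios are simulated with parameters drawn from
log-uniform priors, reduced to ten summaries (per-population expected
heterozygosity and mean minor-allele frequency, multilocus FST,
private-polymorphism fractions, pooled minor-allele-frequency quartiles),
and the nearest fraction of simulations by SD-normalized Euclidean distance
is accepted; posterior model probabilities are acceptance shares and
goodness-of-fit is the posterior-predictive quantile of the observed
distance to the accepted cloud.  The production default of 1e6 simulations
per scenario is a convention inherited from rejection-ABC practice; the
package's tests run the same machinery at a few hundred simulations, which
suffices for well-separated scenarios.

## Synthetic data

Every input the pipeline consumes can be generated in code, deterministically
given a seed: coalescent genotypes under any model of the family
(`simulate_genotypes()`), symmetric-island neutral loci
(`simulate_island_genotypes()`), hybrid swarms with known categories built
from explicit gamete draws (`simulate_hybrid_swarm()`), two-clade mtDNA-like
alignments under a symmetric substitution model (`simulate_mtdna()`), and a
pre-QC fixture with one planted violation set per filter rule and an
independently recomputed ground-truth attrition report (`make_qc_fixture()`).
Loci are unlinked (independent gene trees), matching both the effective
independence of LD-pruned DArT tags and the independence assumption of the
composite likelihood.

What the generators deliberately do **not** emulate: linked loci and
recombination tracts, sequencing-error processes beyond the missingness and
depth metadata fields, ascertainment beyond segregating-site conditioning,
and selection.  Tests passing on these simulations therefore demonstrate
correctness of the estimators under their own assumptions — they do not
certify robustness to linkage, allele-calling error, or selection in real
datasets.

## Problem sizes and runtime choices

The shipped tests use sizes chosen to exercise each method meaningfully on a
single CPU: QC fixtures of ~85 loci × 40 individuals; differentiation checks
at 500-4000 loci; outlier scans with 1e4-locus null tables; hybrid
classification with 2-3 chains of 800-1500 sweeps on 100-300 loci; and
demographic recovery experiments with 2000 segregating loci at projection
(20, 20), three simulate-and-refit replicates per model, reporting the
median recovered split time.  At those sizes the split-time estimator is
median-unbiased but individual fits occasionally collapse into the
short-split basin; the replicate median is the designed guard, and
`fit_result$trace`, `at_bound` and the split-time profile make such
collapses visible.  Production analyses should raise `n_screen`,
`finish_replicates`, the FDIST null size (1e5) and the Gibbs chain lengths
to their defaults or beyond.

## Known limitations

* The expected-AFS engine is Monte-Carlo: likelihood values carry a frozen
  seed-dependent error (a few units at 5e4 genealogies for a 2000-SNP
  spectrum), so small AIC differences between models should not be
  over-read.
* Composite-likelihood theory is used for point estimation and AIC ranking
  only; no Godambe-adjusted uncertainties or bootstrap intervals are
  provided.
* Split times much larger than the within-population coalescent scale are
  weakly identified when recent migration is strong (the profile likelihood
  over T1 flattens); replicate fits and the reported profile are the honest
  diagnostics.
* The AMOVA implementation covers one grouping level (among/within
  populations), not nested regional designs.
* `fdist_null()` assumes equal deme sizes and stationary structure; it
  calibrates mean FST but not higher moments.
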