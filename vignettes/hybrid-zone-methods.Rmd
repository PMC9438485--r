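---
title: "Methods: genomic clines, sex-linked marker behavior, and windowed divergence in ZW hybrid zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic clines, sex-linked marker behavior, and windowed divergence in ZW hybrid zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hzclines analyses hybrid zones between two divergent lineages — called
*inland* and *coastal* throughout — in a ZW (female-heterogametic) system
genotyped with short reduced-representation sequencing tags (~69 bp, one or
a few SNPs each).  This vignette is the package's own account of the models
it fits, the rules it applies, the parameters that matter, and the
boundaries of what its validation on synthetic data does and does not show.

## Data model

Genotypes are alt-allele dosages: 0 (hom-ref), 1 (het), 2 (hom-alt), or
missing.  Hemizygous calls (the single Z of a female, W-linked loci in
females) are carried in the same coding as 0/2, which is how genotyping
pipelines report them and how all dosage-based statistics here consume
them.  Marker coordinates are 0-based internally and windows are half-open;
1-based inputs are converted at the I/O boundary.  Phasing is ignored.

Samples carry sex (F/M), mitolineage (inland/coastal, i.e. the maternally
inherited mtDNA clade), and one of four population classes: `pure_inland`
and `pure_coastal` (allopatric sites where one mitolineage occurs) and
`hybrid_inland` / `hybrid_coastal` (sympatric, hybrid-zone sites, labeled
by the individual's own mitolineage).

## Behavioral classification of sex-linked markers

In a ZW system, a W-linked marker is present in females and missing in
males; a Z-linked marker appears homozygous in (hemizygous) females while
males can be heterozygous.  `classify_consensus()` applies these rules
separately within each population class and then requires cross-population
agreement:

* **W-behaving**: at least 90% of females called *and* at least 90% of
  males missing (the 10% slack is `error_tolerance`, absorbing genotyping
  error and stray missingness).
* **Z-behaving**: at least 90% of *called* females homozygous, *and*
  heterozygotes in at least 10% of called males (`min_male_het`), which
  keeps monomorphic, autosomally behaving markers from slipping through.
* **autosomal-like**: well called in both sexes and neither rule fires.
* **indeterminate** otherwise.

A population with fewer than `min_called = 5` called females (or scored
males) is skipped as no-data rather than letting small-sample noise veto
the consensus.  The consensus is W- or Z-behaving only when *every*
population with sufficient data agrees; disagreement, or an indeterminate
label in a population with data, yields `unclassified`, and such markers
should be excluded downstream.  The same rule set is applied to markers
anywhere in the genome, including neo-sex-chromosome candidates: a former
autosome fused to the W yields a female-limited copy (W-behaving markers
mapping to that autosome) and an unfused counterpart that behaves like a Z.

The homozygosity criterion is evaluated among called females only, with the
10% tolerance applied to the homozygote fraction; "presence" in the W rule
means any non-missing call, since hemizygotes typically score as
homozygotes and requiring a particular coding would be redundant.

## Differentiation and divergence

`fst_per_snp()` implements the two-population Weir–Cockerham (1984)
variance-component estimator θ = a/(a+b+c) directly from genotype counts.
Markers are filtered per pairwise comparison: pooled minor-allele frequency
must exceed 0.05 (low within-population polymorphism inflates F_ST), the
missing fraction must be below 50%, and markers on the neo-sex chromosome
face a stricter 10% missingness ceiling because their behavioral
classification depends on call completeness.  Counting "strongly
differentiated" markers uses an inclusive θ ≥ 0.2 threshold.  All markers
are treated as diploid, including hemizygous female calls; this inflates
apparent homozygosity at sex-linked loci and is a documented bias shared
with the dosage coding itself.

`dxy_windows()` and `pi_windows()` compute absolute divergence and
diversity from tag sequences rather than SNPs alone: per SNP, the
between-group mismatch probability is `pA(1-pB) + pB(1-pA)` (or the
sample-size-corrected heterozygosity `2p(1-p)·n/(n-1)` over `n = 2·n_called`
allele copies for π); per tag these are summed and divided by the tag
length, so tag bases without SNPs count as invariant sites.  Windows are
100 kb sliding by 50 kb (tags are sparse, so windows must be large enough
to hold several tags, and the half-overlap smooths coverage noise); a tag
belongs to a window if its mapped start position lies inside it, with no
pro-rating across edges — overlapping windows absorb the edge effects.  A
tag with no computable SNP in the group(s) under comparison is skipped
entirely, and π requires at least two called individuals, since a single
diploid only exposes its own heterozygosity.  Windows report per-site
values in [0, 1] together with their tag count and base total.

Supporting operations mirror standard practice: uniform random subsampling
of males down to female sample sizes (`subsample_group()`, seed-stable)
separates sex-specific signal from sample-size artefacts; Spearman rank
correlation between θ and per-marker missingness (`missingness_fst_correlation()`)
diagnoses missingness-inflated differentiation (ranks because the θ
distribution is strongly skewed); and `thin_markers()` retains one marker
per 100 kb bin per chromosome to limit linkage, with the neo-sex chromosome
exempt when its architecture is the object of study.

`permuted_fst()` builds the null distribution of θ by reassigning the
pooled individuals of a comparison to pseudo-groups of the original sizes;
when the comparison is sex-specific the permutation stays within that sex.
Distribution-level contrasts (e.g. female-vs-female θ against male-vs-male
θ) use the unpaired two-sided Mann–Whitney test with tie correction.

## Hybrid index

`hybrid_index()` estimates, per individual, the proportion *h* of inland
ancestry by maximum likelihood under the allele-copy model
`q_l(h) = h·p_inland,l + (1-h)·p_coastal,l`: diploid loci contribute
binomial genotype probabilities at q_l(h), female-hemizygous loci a
Bernoulli term.  Parental frequencies come from the pure classes with a
+0.5/+1 pseudocount so that near-diagnostic loci never assign zero
probability to an observed genotype.  Only informative loci (parental
frequencies differ) enter; missing genotypes are skipped; samples with no
informative called locus are dropped with a warning.  Optimization
evaluates a 101-point grid to bracket the maximum — guarding against
non-unimodal profiles — and refines by golden-section search to 1e-8, with
endpoint checks so fully parental samples reach exactly 0 or 1 within
optimizer tolerance.  The reported interval is the profile-likelihood
region within 1.92 log-units of the maximum (the asymptotic 95% cutoff).

## Genomic clines

A genomic cline is the relationship between genotype-class probability at a
locus and *h*.  `genomic_cline()` fits a baseline-category multinomial
logit — `log(P(k)/P(0)) = β0_k + β1_k·h` for diploid categories, a plain
logistic for haploid loci — by Newton–Raphson.  The linear term in *h* is
the smallest model that expresses the cline shapes of interest
(directional shifts, heterozygote deficit under underdominance,
heterozygote excess under overdominance).  The fit statistic is
`2·(logL_fitted − logL_intercept-only)`: a locus whose genotypes relate to
*h* no more than exchangeably has no gain beyond chance.

The neutral reference is *not* a χ² distribution — neutral admixture itself
produces a strong genotype–*h* relationship — but a permutation null:
`cline_permutation_test()` shuffles the genotype vector across individuals
(decoupling genotype from *h* while preserving both margins), refits, and
reports `p_perm = (1 + #{permuted ≥ observed})/(1 + n_perm)` with 1000
replications per locus by default.  Significant loci are those whose
genotype–*h* coupling is stronger than any exchangeable arrangement —
the signature of restricted gene flow at that locus.

Numerical choices: coefficients are capped at ±25 on the logit scale so
completely separated loci (e.g. a diagnostic locus in a sharp zone) stay
finite and rank-comparable within the permutation distribution (such fits
are flagged); Newton steps are halved when the likelihood would decrease;
convergence is declared below 1e-10 log-likelihood change.  Z-linked loci
are haploid in females and codominant in males; per-sex runs are the
default (mirroring the sex-stratified design), and the mixed-ploidy model
fits female-haploid and male-diploid likelihood blocks sharing *h* with
separate coefficients, summing the gains.  Per-marker permutation seeds
are derived deterministically from the master seed and the marker name, so
results do not depend on marker order.

Fixed-difference filtering of cline loci is deliberately *not* applied:
marker behavior in the parental populations does not necessarily inform on
hybrid-zone dynamics, and near-diagnostic frequencies (with pseudocounts)
drive the model instead.

## Ancestry, divergent blocks, and the mitolineage association

`ancestry_matrix()` labels, per marker, the allele with the higher inland
parental frequency as inland-ancestry when the parental frequencies differ
by at least `delta_min` (default 0.3 — far enough apart that the
assignment is meaningful at reduced-representation error rates), then maps
each genotype to its inland-allele dosage; heterozygous calls at
female-haploid loci are data conflicts and become unassigned.

`detect_divergence_block()` looks for the windowed signature of a
non-recombining divergent block (e.g. an inversion): windows whose mean
per-SNP θ is at least 0.2 *and* whose minimum per-tag D_XY clears the
chromosome-wide lower decile — an *absence of low-divergence tags*, which
distinguishes a block from incidental high-θ markers sitting amid ordinary
shared polymorphism.  Flagged windows are merged, bridging gaps of at most
one window.  Single-window flags from sampling noise can survive this
filter; interpretation should rest on multi-window intervals and on the
allopatric-vs-parapatric contrast, not on isolated windows.

`call_block_haplotypes()` summarizes each individual's block as the
fraction *f* of inland alleles across its called block markers: inland if
f ≥ 0.8, coastal if f ≤ 0.2, heterozygous otherwise, uncalled below 5
markers.  The 0.8/0.2 thresholds and the 5-marker floor are free
parameters with no canonical values; sensitivity to them should be
reported alongside results.  Hemizygous females are expected to come out
inland or coastal; the heterozygous category remains permitted for them
because conflicting calls (genotyping error, or a true recombinant) do
occur and deserve visibility rather than silent coercion.
`mito_block_association()` tabulates block haplotype by sex and
mitolineage with within-row proportions, uncalled individuals excluded
from denominators and reported separately.

## The synthetic hybrid-zone generator

`simulate_dataset()` is first-class, tested code: it generates the study
conditions against which everything above is validated, with full ground
truth.  Its defaults emulate a two-mitolineage ZW hybrid-zone design:

* **Group sizes**: 72/54/55/110 males and 41/24/40/46 females across
  pure-inland, hybrid-inland, hybrid-coastal, pure-coastal (442 birds),
  the sex skew reflecting call-playback field sampling.
* **Markers**: 600 autosomal, 300 Z-linked, 40 W-linked (mismapped to
  autosomes, as W tags cannot map to a male reference), 40 neo-W, 180
  neo-Z off-block and 160 block markers — about 1/10 to 1/100 of a real
  reduced-representation panel, preserving the W:Z class proportions.
* **Parental frequencies**: each marker draws a shared ancestral frequency
  from a Beta(0.8, 0.8) rescaled into [0.2, 0.8], then each lineage drifts
  by Normal(0, 0.1), clamped to the range.  Most markers are therefore
  weakly differentiated, none fixed — matching the empirical situation
  where fixed differences between lineages are nearly absent and θ ≥ 0.2
  sits above the 99th percentile of genome-wide differentiation.  The
  [0.2, 0.8] range encodes SNP-panel ascertainment (markers are discovered
  as polymorphisms) and guarantees that Z-linked loci show the male
  heterozygosity on which behavioral classification relies.
* **Hybrid indices**: pure classes sit at h = 1 or 0; hybrid classes draw
  from Beta(8, 2) (inland) and Beta(2, 8) (coastal) — hybrid-zone birds
  remain dominated by their own lineage's ancestry.
* **The block**: an 8 MB interval (51–59 MB) on the 73 MB neo-Z.  Each
  haplotype copy carries an inland/coastal *type* inherited as a unit (no
  recombination); conditional on type, each block locus draws its allele
  from near-fixed type-specific frequencies (0.8/0.2 by default, i.e. low
  within-type polymorphism; setting them to 1/0 gives fully fixed,
  perfect-LD haplotypes).  The default density of 20 block markers per MB
  makes the mean gap between adjacent block markers equal the 50 kb window
  step, so the block is localizable at window resolution.  By default
  block copies follow the individual's h; `block_hybrid_freq` instead
  gives both hybrid classes a shared block frequency, making block
  genotype independent of mitolineage for association analyses with known
  truth.
* **Selection**: per-locus regimes re-weight genotype probabilities at
  sampling time — underdominance multiplies the heterozygote probability
  by (1−s) and renormalizes, overdominance by (1+s), directional selection
  shifts the effective h by the configured offset, clamped to [0, 1].
  This produces genotype–h associations of known shape without a forward
  population model, which is exactly what cline validation needs.
* **Noise**: miscalls (1% default; a miscall becomes one of the other two
  codes at random, so hemizygotes can err into apparent heterozygotes) and
  missingness (5% default, missing-completely-at-random within
  (marker, group) strata, the minimal structure reproducing
  group-varying missingness patterns) are injected last.

Everything is bit-reproducible from the seed, with per-stage seeds derived
deterministically so stages can be regenerated in isolation.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about field data: linkage disequilibrium outside the block
(markers are independent given h), geographic/spatial structure within
population classes, related individuals, locus-specific error or
missingness pathologies (allele dropout correlated with genotype),
reference bias, and multi-SNP tags (each simulated tag carries one SNP;
the window machinery itself is validated on constructed multi-SNP tags).
Recovery rates measured on synthetic data are upper bounds for real
datasets.

## Problem sizes used in validation

The test suite and the acceptance script validate at deliberately modest,
fixed sizes chosen to exercise every code path at full statistical
strength: exhaustive θ oracle sweeps at ≤ 6 individuals per group;
classification at the full 442-sample design; hybrid-index recovery at 200
hybrids × ~500 thinned strongly informative loci (Δp = 0.6, where the
per-locus Fisher information makes RMSE < 0.05 attainable); cline
calibration at 200 null loci × 500 permutations and power at 50
underdominant loci (s = 0.8) × 120 hybrids; and the end-to-end pipeline on
a bundled ~300-marker, 112-sample configuration.

## Known limitations

* Diploid coding of hemizygous calls biases sex-linked θ, D_XY and π; the
  package follows the field convention and documents rather than corrects
  it.
* The cline model is linear in h on the logit scale; strongly asymmetric
  or epistatic cline shapes are detected (the permutation test is shape-
  agnostic in its statistic) but not parameterized.  The model degree is
  a natural extension point.
* Block detection reports candidate intervals, not significance; its
  thresholds (θ floor 0.2, lower-decile D_XY) are screening heuristics.
* The Mann–Whitney distribution comparison treats markers as independent;
  linked markers overstate its effective sample size.
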