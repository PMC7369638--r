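---
title: "Models and methods behind svstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svstrat)
```

svstrat analyses structural-variant (SV) genotype matrices across many
populations. This vignette is the package's own account of the statistics
it implements, the conventions it had to fix where the field leaves room,
and what its synthetic cohorts do and do not emulate.

## Data model

A callset is a set of variants (0-based half-open intervals; insertions are
anchored at one base and carry their insert length separately) crossed with
samples. Biallelic variants carry dosages 0/1/2 with phred genotype
qualities (GQ); multiallelic copy-number variants carry diploid copy
numbers (CN) with phred copy-number qualities (CNQ). Missingness is an
explicit `NA`, never a numeric sentinel, so no statistic can silently
absorb a missing call. Which field a statistic uses (dosage or CN) is
always an explicit argument. Sex chromosomes are read and written but
excluded from all statistics by default; the analyses here are autosomal.

Two phred thresholds recur. GQ < 20 masks a biallelic call
(a 1% error ceiling), and CNQ ≥ 13 marks a high-confidence copy-number
call, since `1 − 10^(−13/10)` ≈ 0.95. A stricter CNQ > 12 floor governs
fragment merging.

## Quality control

**Coverage screening.** Cell-line cohorts accumulate culture artifacts,
predominantly chromosome gains. Binned depth is normalised by each sample's
genome-wide median and smoothed with a centred rolling mean (default 10
bins). Runs of at least 20 bins beyond 1.35 (gain) or 0.65 (loss) are
flagged; a chromosome with ≥ 90% of bins beyond threshold is flagged whole.
The 1.35/0.65 defaults sit between the full-trisomy/monosomy ratios
(1.5/0.5) and the noise band around 1.0, so mosaic events at intermediate
ratios are still separable; they are package conventions, exposed as
arguments, standing in for what is otherwise a manual inspection step.
Samples flagged on two or more distinct autosomes are excluded outright;
other flagged samples have the affected region (the whole chromosome, for
whole-chromosome flags) masked to missing.

**Excess heterozygosity.** The batch-artifact failure mode in
mixed-library cohorts is a variant called heterozygous across most of one
library preparation. We use the exact conditional Hardy–Weinberg
distribution of the heterozygote count given the allele counts (the
Levene/Haldane distribution) and compute the one-sided tail probability of
at least the observed number of heterozygotes. A variant is removed when
this p-value falls below a per-batch threshold in any batch (defaults:
1e-3 for small PCR batches, 1e-5 for large PCR-free batches, 0.05 for a
batch of fewer than ten samples) or below 1e-5 across the whole dataset.
Batches with fewer than two genotyped samples are skipped with a warning.

## Stratification statistics

**Frequencies.** Allele frequency and missingness are computed per
population after GQ masking; a population×variant cell with missingness
above 25% is recorded `NA` rather than dropped.

**Hudson Fst.** Per site, numerator
`(p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)` and denominator
`p1(1−p2) + p2(1−p1)` (allele counts `n`); pairs are aggregated as the
ratio of sums. This estimator was chosen for its low bias with two
populations and unequal sample sizes; the aggregation makes the mean
insensitive to near-monomorphic sites, which are excluded when the
denominator is zero.

**Max-AF-difference scan.** For every population pair, the maximum
per-variant allele-frequency difference is placed against the pair's mean
SNV Fst. The SNV distribution is the conservative null axis: neutral
variants drift alike regardless of mutational class. Pairs containing a
population of ≤ 10 samples are flagged and excluded from trend fitting;
the LOESS curve drawn by `plot_strat_scan()` is descriptive only — outlier
calls are made by the permutation test.

**Vst.** `Vst = (V_T − V_S)/V_T` with population variances (divide by n)
and a size-weighted within-group average; defined 0 when `V_T = 0`. For
biallelic variants Vst is computed on dosages as pseudo copy numbers — the
natural choice for a genotyped deletion, and the one that keeps the
statistic comparable across variant classes. The permutation test permutes
population labels B = 1000 times and reports `(k+1)/(B+1)`, whose floor
1/1001 ≈ 0.001 matches the smallest p-value such a design can report.

**PBS.** `T = −log(1 − Fst)` per pair, `PBS = (T_fs + T_fo − T_so)/2`.
Variants are filtered to pooled minor allele frequency ≥ 1% and
missingness ≤ 10% across the triple; the triple itself is always an
explicit argument because reasonable analyses differ in the choice of
sister and outgroup. Negative per-variant Fst estimates are clamped to 0
inside the log transform only; raw values are retained everywhere else.
Ranks are the fraction of a caller-supplied null distribution (intended:
SNV PBS values) at or below each variant's PBS, with ≥ 99% flagged.

One numerical consequence of the clamp deserves note: when all three Fst
estimates are non-positive the PBS is exactly 0, so under a structureless
cohort the statistic has a point mass at zero and the deterministic rank is
conservative (inflated) on that atom. `pbs_scan(rank_ties = )` therefore
also offers midranks and a randomized quantile rank; the randomized rank is
exactly uniform under the self-null and is what the calibration tests use,
while the default deterministic rank agrees with it away from ties and
never deflates a rank — the 99% flag is unaffected.

**Private variants.** A variant is private to a population (or region)
when all carriers — dosage ≥ 1, or copy number different from the global
modal CN for multiallelic variants — fall in that unit, and there are more
than two of them. At region level, samples whose own-region admixture
fraction is below 0.8 are removed first, since one admixed genome can
dissolve regional privacy. Adjacent fragments with the same copy number (or
class), allele frequencies within 0.05, and gaps ≤ 25 kb are collapsed into
one counted unit first; the 0.05 tolerance is a package convention — tight
enough to chain fragments of one event, loose enough for sampling noise.

## Callset engineering

Reciprocal overlap is `min(|a∩b|/|a|, |a∩b|/|b|)`. Cross-callset matching
declares a locus shared when any partner variant reaches the threshold
(0.3 for cross-study comparison, 0.5 within-study), ignoring the variant
class by default because callers disagree on class labels at shared loci;
class-aware matching sits behind a flag. Per-sample fragment merging chains
calls with CNQ strictly above 12, identical copy number and gaps ≤ 50 kb,
transitively, taking the minimum CNQ; cross-sample merging collapses only
exactly identical intervals of the same class. All merges are idempotent
and order-independent given the same input set.

## Archaic introgression

Archaic genomes enter as pseudo-diploid CN calls per variant. States are
assigned by comparing CN to the locus's reference-diploid expectation
(2 unless annotated otherwise, for segmental-duplication loci); calls below
CNQ 13 are MISSING and never guessed. The candidate chain requires
Vst > 0.2, a direction-matched archaic state (a deletion candidate needs an
archaic deletion), and African frequency ≤ 0 by default. The African
tolerance is an explicit argument rather than a judgment call, since
real analyses occasionally keep a candidate with a few percent African
frequency; the complementary "ancestral" set collects variants carried
only by Africans and at least one archaic genome. The three filters
commute.

## Runaway expansions

Per-population CN histograms are built over CNQ ≥ 13 calls with the pooled
modal CN (ties resolve downward so duplications register as expansions). A
(variant, population) pair is a runaway call when ≥ 10% of the population
sits at CN ≥ modal + 2 while the same fraction outside the population is
below 5%. These three numbers are package conventions — the phenomenon is
described in the literature through examples (haptoglobin-related,
olfactory-receptor and sulfotransferase loci expanding to 9–18 copies in
single regions against a global modal of 2–3), and all the described
examples fall well inside these defaults; every threshold is an argument.
With phased haplotype CNs, equal expanded haplotypes are flagged as a
homozygous runaway haplotype; without phase, only a high-CN flag is
possible.

## The synthetic cohort generator

No public generative model exists for these cohorts, so the generator's
parameters are package conventions, fixed once:

* **Structured frequencies** follow the Balding–Nichols model: ancestral
  frequency `p ~ Beta(1, 3)` (clipped to 0.01–0.99; a low-frequency-skewed
  spectrum), per-population frequency
  `Beta(p(1−F)/F, (1−p)(1−F)/F)`. `F` is the drift parameter; pairwise
  Hudson Fst between two populations recovers `F`, which is what the
  calibration tests assert (±0.02 at 5,000 variants, 50 samples per
  population).
* **Genotypes** are Hardy–Weinberg within population. Qualities are
  discretised Gammas: GQ ~ Gamma(shape 4, scale 15), putting ≈ 5% of calls
  below 20, and CNQ ~ Gamma(4, 9.75), ≈ 5% below 13 — enough to exercise
  every masking path without dominating the data. Missingness 2%.
* **Multiallelic ladders**: haplotype 1 is fixed at single copy; haplotype
  2 carries at most one minor ladder allele (0 or 2 copies) at a
  Balding–Nichols frequency (ancestral mean 0.15), so default diploid CNs
  enumerate to {1, 2, 3}. Homozygous minor alleles are not generated in the
  default regime (recurrent low-frequency mutation); runaway injection
  overrides this with a high-copy haplotype (default 9, diploid 18 when
  homozygous) in a configured fraction of one population.
* **Introgression injection** rewrites a neutral variant: frequency 0 in
  every African-region population, Hardy–Weinberg at the configured
  frequency in the target region, 0 elsewhere; the named archaic genomes
  become homozygous non-reference with CNQ ≥ 13. Carriers are resampled
  until at least one exists, so an injected variant is always observable.
* **Batch artifacts** force every sample of one batch heterozygous at
  selected variants — exactly the failure mode the ExcHet filter targets.
* **Coverage** is a diploid baseline with multiplicative lognormal noise
  (sd 0.05) over 22 × 50 one-megabase bins; aneuploidies scale a
  chromosome (or its leading fraction) by 1.5, 0.5, or an intermediate
  mosaic ratio.

All randomness flows from one seed; identical configurations produce
identical cohorts. `make_fixtures()` freezes the cohort used throughout
the test suite: six populations of 30 in four regions (African and
Oceanian analogues included), 200 biallelic and 20 multiallelic variants,
two archaic genomes, two injected introgression variants (0.63 in the
Oceanian analogue shared with "Denisova"; 0.4 in the East-Asian analogue
shared with "Neanderthal"), one runaway, one batch artifact, two private
variants, three admixed samples and one chr9 trisomy.

What the generator does **not** emulate: linkage and haplotype structure
beyond the single runaway haplotype, sequence-level breakpoints and
repeat context, caller-specific error modes (fragmenting of large CNVs is
modelled only through the merge operations' own tests), reference bias,
and admixture-graph history richer than one-way region admixture
fractions. Tests passing on these cohorts therefore validate the
statistical machinery and the filter semantics, not caller behaviour on
real sequence data.

## Numerical and design choices

* Vst uses a one-pass group decomposition for the permutation inner loop
  (all B permutations evaluated as one matrix product per test); agreement
  with a two-pass oracle is asserted to 1e-10 absolute, the right scale for
  a statistic bounded by 1.
* The permutation p-value uses the add-one estimator; ties (`permuted ≥
  observed`) count against the variant, so the test is conservative for
  discrete data.
* Degenerate inputs are explicit: Vst is 0 when total variance is 0;
  `Fst = 1` is an error inside PBS (infinite branch); monomorphic pairs are
  excluded from Fst aggregation; empty mask sets and empty candidate sets
  round-trip as empty tables with headers.
* Modal-CN ties resolve to the lower copy number, so borderline
  duplication spectra count as expansions rather than vanishing.
* Merging chains are computed within (chromosome, CN) groups against the
  running chain end, which makes them transitive and input-order
  independent.
* Test and calibration problem sizes (2,000 null variants at B = 199 for
  type-I calibration, where the add-one estimator makes the nominal 0.05
  level exactly attainable; 5,000 variants for Fst recovery; 1,000 random
  instances per oracle) were chosen as the smallest designs that give the
  assertions comfortable statistical margins.

## Limitations

The pipeline analyses genotyped callsets; it does not discover variants,
remap reads, or validate breakpoints. PBS interpretation depends entirely
on the supplied null distribution — with the self-null it is a relative
ranking, not a test against neutrality. The runaway rule and the coverage
thresholds are conventions standing in for manual curation and should be
re-examined before being applied to a cohort whose noise structure differs
from the generator's assumptions.
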