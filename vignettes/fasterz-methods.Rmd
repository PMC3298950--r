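---
title: "Methods: Z-versus-autosome polymorphism and divergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Z-versus-autosome polymorphism and divergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasterz)
```

## The scientific problem

In birds and other female-heterogametic taxa, the Z chromosome is carried
twice by males and once by females. At a balanced sex ratio its effective
population size is 3/4 of the autosomal one, so under neutrality and equal
mutation rates Z-linked nucleotide diversity is expected to be 75% of
autosomal diversity, while between-species divergence should not differ by
chromosome class. Published multilocus surveys of the four black-and-white
*Ficedula* flycatchers (and of other congeneric birds) instead report Z:A
diversity ratios below 0.75 together with *elevated* Z-linked divergence —
a pattern compatible with either faster-Z evolution (hemizygous exposure,
stronger drift, male-biased mutation) or with differential introgression
(autosomal gene flow after secondary contact, with Z-linked gene flow
blocked by sex-linked incompatibilities).

`fasterz` implements the complete statistical battery used to characterise
this contrast from multilocus phased haplotype alignments, plus a
structured-coalescent isolation-with-migration (IM) simulator that
generates synthetic datasets with the statistical structure the analysis
assumes, so every test in the battery can be calibrated against data whose
generating process is known.

## Data model and missing-data policy

A `locus_alignment` holds one locus: a haplotype-by-site character matrix
over `A/C/G/T/N/-` plus per-haplotype metadata (individual, species,
population, sex, ingroup/outgroup role). Validated invariants: one shared
alignment length; on Z-linked loci each ingroup female contributes exactly
one haplotype (hemizygosity) and each male two; on autosomal loci two per
individual; outgroup individuals one. IUPAC ambiguity codes other than N
are rejected because inputs are phased haplotypes, not genotype consensus
sequences.

All statistics operate on **complete sites**: columns containing only
A/C/G/T across the haplotypes being analysed (complete-case deletion per
site). This makes S, the mean pairwise difference k, per-site diversity
statistics and the site-classification counts mutually consistent on a
single surveyed length `L_surveyed`. Pairwise analyses use the joint
complete-site set of both samples (and the outgroup where one is used), so
category counts and d~xy~ share a denominator. Sequences of one locus from
different sources are adjusted to the shortest length before analysis
(`trim_to_common_length`), mirroring the usual Sanger-era alignment
convention. Site indices are 1-based throughout, as is natural in R.

## Diversity statistics

Per population and locus (`summarize_population`):

* `S` — segregating sites (multiallelic sites count once);
* singletons — sites where exactly one haplotype differs from all others
  (folded definition, `n - max(allele count) == 1`, computable without an
  outgroup);
* `k` — mean pairwise differences over all n(n−1)/2 haplotype pairs; any
  allele mismatch counts one difference. Computed from allele counts, never
  back-derived from rounded per-site values;
* `pi = k / L_surveyed`;
* Watterson's `theta_w = S / (a1(n) L)` with `a1(n)` the (n−1)-th harmonic
  number;
* Tajima's `D = (k − S/a1) / sqrt(e1 S + e2 S(S−1))` with the standard
  sample-size coefficients; undefined (reported as a dash) when S = 0.

Report writers round pi and theta to 4 decimals and D to 3, matching the
conventions of the published flycatcher summary tables shipped under
`inst/extdata/` as worked-example fixtures. Multi-locus totals are computed
by pooling complete sites across loci — `sum(S_i) / sum(a1(n_i) L_i)` for
theta, length-weighted for pi — since per-locus sample sizes differ.

## Site classification between species

On the joint complete sites of a species pair, each variable or
differentiated site falls in exactly one category: **shared** (polymorphic
in both), **exclusive** to one sample (polymorphic in exactly one; this
includes sites where the monomorphic sample carries an allele absent from
the polymorphic one — the standard convention), or **fixed** (each sample
monomorphic, for different alleles). `d_xy` is the mean between-sample
pairwise difference. Divergence to the outgroup (`outgroup_divergence`)
counts sites where the single outgroup haplotype carries an allele absent
from the focal sample; this definition is a package decision — variants
based on the sample consensus exist — and is stated here because published
tables rarely define their divergence column.

Per pair and chromosome class, `pair_summary_table` reports mean ± SE of
shared and fixed counts across loci and pools the fixed:shared 2×2 table
for a two-sided Fisher's exact test contrasting Z against A.

## The Z-versus-autosome test battery

* **Polymorphic-site Fisher test** — 2×2 contrast of pooled segregating
  versus monomorphic site counts between the Z-linked and autosomal
  compartments. Two-sidedness follows the probability-mass convention
  (all tables with point probability ≤ the observed one), the convention
  under which the published per-population p-values reproduce exactly.
  The test assumes independent sites; its size was checked by simulation
  under binomial site sampling (rejection rate 3–7% at α = 0.05), which is
  the sampling model the test itself posits. Coalescent data violate site
  independence, which is precisely why the ratio tests below are calibrated
  against the coalescent simulator instead.
* **Z:A ratio t-test** — each Z locus's diversity divided by the pooled
  autosomal diversity, tested against 0.75 with a two-sided one-sample
  t-test (df = number of Z loci − 1). Both theta_w and pi are supported;
  the ratio denominator always pools all autosomal loci. The degenerate
  all-ratios-equal case is reported as t = 0, p = 1 on the null value. The
  unit of "locus" is whatever the locus table supplies, so amplicon-level
  and gene-level groupings are both expressible.
* **Fisher's combined probability** — χ² = −2Σlog p on 2k df, for
  combining the per-population tests.
* **Paired t-test** — Z versus A F~ST~ per species pair.

## Multilocus HKA test

Under neutrality, polymorphism and divergence are proportional across
loci. With phi_i = theta_i · h_i (inheritance scalar h = 0.75 for Z, 1 for
A), the expectations are E[S1_i] = phi_i a1(n1_i), E[S2_i] = f phi_i
a1(n2_i), and E[D_i] = phi_i (T + (1+f)/2), with the classical variances
Var = E + (phi·…)². The goodness-of-fit statistic X² sums
(obs − exp)²/var over all compartments.

Two divergence modes are supported, because source datasets differ in how
the divergence column is built: *outgroup mode* (n2 = 1; divergence is the
mean difference of the focal sample to a single outgroup haplotype; f is
not identifiable and fixed at 1) and *two-species mode* (polymorphism in
both species, divergence the mean between-species pairwise difference).

**Estimation.** Parameters solve the classical method-of-moments system:
given (T, f), each locus's phi_i follows in closed form from its total
count, and the pooled polymorphism constraints pin down T (monotone in the
pooled equation — solved by bisection) and f (2-parameter Nelder–Mead in
two-species mode). This was chosen over generic minimisation of X² itself
because the p-value machinery refits the model to every one of the
simulated null datasets — 250,000 refits in the calibration experiments —
and the moment solution is deterministic, well-conditioned and orders of
magnitude cheaper, while coinciding with the moment equations the
statistic was built around. Loci with zero total counts contribute zero to
X² (their variance is zero by construction).

**Significance.** `hka_pvalue` simulates neutral coalescent datasets at
the fitted parameters (matched sample sizes and inheritance scaling),
refits each, and reports the proportion of simulated X² at least the
observed one. Results are bit-reproducible under a fixed seed. Calibration
(500 neutral replicates × 500 inner simulations, 6 loci, n = 20) puts the
empirical type-I error at α = 0.05 inside [0.03, 0.07]; the slight
conservatism typical of parametric bootstraps at fitted parameters is
visible but mild.

## Population structure

Distances are raw pairwise difference counts summed over loci on each
locus's joint complete sites (no substitution-model correction), matching
the default of the standard molecular-variance software. Combining loci by
summed distances is equivalent to concatenation and reflects the pooled
"Z-linked dataset" / "autosomal dataset" analysis design.

`pairwise_fst` is the distance-based Φ~ST~ from the two-level AMOVA
decomposition, with p-values from permuting haplotypes between populations
((count + 1)/(n_perm + 1), one-sided: permuted Φ ≥ observed). The
haplotype-frequency flavour of F~ST~ is the same computation on the 0/1
"different haplotype" distance, i.e. `pairwise_fst((D > 0) * 1, …)`; the
distance-based statistic is the default because intron haplotypes carry
informative pairwise depths.

`amova` partitions variance into four nested levels — between species,
among populations within species, among individuals within populations,
within individuals — using the nested expected-sums-of-squares system for
unbalanced designs (group-size coefficients of Searle's nested ANOVA).
Negative components are reported as computed, not truncated, and
percentages are taken on the signed components, whose sum equals the total
variance exactly (asserted to 1e−9 in the tests). Hemizygous females
contribute one haplotype and no within-individual pairs; the df bookkeeping
follows the realised counts. Permutation schemes per level: populations
among species; individuals among populations within species; haplotypes
among individuals within populations; and, for the within-individual
component, haplotypes across the whole sample, tested on the lower tail
(structure manifests as a deficit of within-individual variance).

## Recombination filtering

`four_gamete_rm` applies the four-gamete test to all pairs of biallelic
complete sites and computes R~M~, the minimum number of recombination
events, as the maximum set of non-overlapping incompatible intervals
(greedy scan by right endpoint — optimal for interval scheduling).
Because a non-recombining coalescent model is fitted downstream, sites
carrying the recombination signal are removed: the filter greedily drops
the site participating in the most incompatible pairs until none remains,
which removes few sites and guarantees R~M~ = 0 afterwards. The published
description of this step ("sites with recombination were excluded") is
ambiguous between removing sites and removing intervals; site removal was
chosen as the minimal intervention and is idempotent. The scope (single
population or pooled pair) is a flag, since either may be wanted before an
IM fit.

## The isolation-with-migration simulator

The generator is a backwards-in-time structured coalescent over an
arbitrary set of demes with a merge schedule, with three interfaces:
`simulate_genealogy` (two populations + ancestor + optional outgroup),
`drop_mutations` (infinite-sites Poisson mutation), and
`simulate_dataset` (a full multilocus study design).

Conventions, chosen once:

* **Units.** Genealogy time is measured in units of 2N~e~ generations of
  the reference population; coalescence in a deme of relative size r
  proceeds at rate k(k−1)/(2r); mutations fall at rate theta/2 per lineage
  per unit, so a panmictic pair differs at theta sites in expectation.
  `demographic_units`/`scaled_units` convert exactly between this scale
  and (N~e~, years, per-generation migration) via theta = 4 h N~e~ μ L,
  i.e. 3 N~e~ μ L on the Z; the conversions round-trip to 1e−12.
* **Migration.** `m1` is the backwards rate at which a lineage in
  population 1 traces into population 2 — forward-time gene flow from 2
  into 1, the direction convention of the IM literature's "M1".
* **Z-linkage.** Z loci take theta_site × z_ratio × (μ_Z/μ_A) per site and
  run on a time scale rescaled by z_ratio, so one demographic history in
  generations drives both chromosome classes consistently; females
  contribute one haplotype.
* **Outgroup.** A single extra lineage in its own deme, merged into the
  deepest ancestral deme at its join time.
* **No intra-locus recombination**, matching the assumption of the IM
  model and the purpose of the four-gamete filter.
* **Reproducibility.** One seed; per-locus substreams drawn up front as
  integer sub-seeds, so datasets are byte-identical under a fixed seed
  regardless of evaluation order.

The default study designs emulate the flycatcher survey: 6 autosomal loci
of 358–983 bp and 5 Z-linked loci of 437–1439 bp, 12–16 diploids per
population, per-site autosomal theta 0.004 (the observed per-site
diversities span roughly 0.001–0.006), z_ratio 0.75, mutation rates
1.35×10⁻⁹ (A) and 1.45×10⁻⁹ (Z) substitutions/site/year with a one-year
generation time where absolute units are needed. The six-population design
uses nested species splits (0.1, 1, 1.5, 2 × 2N~e~ generations) with no
gene flow and an outgroup at 8 — deliberately a *classical allopatry*
scenario, the null against which introgression signatures are judged.

What the generator does **not** emulate: intra-locus recombination,
selection and sweeps, sequencing or phasing error, base-composition and
rate heterogeneity along loci, and linked-site effects across loci. Tests
passing on simulated data therefore validate the estimators and the
pipeline plumbing under the stated model, not robustness of the biology to
model violations on real data.

## Calibration experiments and problem sizes

The test suite runs the following simulation studies (sizes chosen to give
tight Monte-Carlo error at interactive runtimes):

* Watterson unbiasedness: 2,000 replicates at n = 30, theta = 5 — relative
  bias < 5%; neutral Tajima's D mean in [−0.2, 0.1].
* Neutral Z:A ratio: 1,000 simulated study datasets; the ratio of the mean
  pooled Z theta to the mean pooled autosomal theta recovers 75% ± 3
  percentage points. The mean of per-dataset ratios is *not* used: with
  ~40–50 segregating sites per compartment it carries a +3–4% Jensen bias
  (E[X/Y] > E[X]/E[Y]) and does not estimate the neutral expectation.
* HKA type-I error: 500 neutral datasets × 500 inner simulations.
* Φ~ST~ permutation null: 200 independent panmictic datasets, 499
  permutations each; p-values uniform (Kolmogorov–Smirnov).
* Isolation trends: shared polymorphisms non-increasing and fixed
  differences non-decreasing in split time over t ∈ {0.1, 0.5, 1, 2, 4} ×
  2N~e~, 500 replicates per point; migration (m = 2) keeps shared
  polymorphism alive at deep splits — the signature separating
  introgression from deep neutral sorting.
* Brute-force oracles: diversity, site classification, distance matrices
  and R~M~ are cross-checked against naive enumeration on random small
  alignments.

One calibration finding is worth recording: with only 5 Z and 6 A loci,
the probability that a single simulated dataset shows pooled Φ~ST~(Z) >
Φ~ST~(A) under equal-length neutral histories saturates near 75–78%
regardless of split depth — the across-locus genealogical variance of a
5–6-locus Φ~ST~ is irreducible. The expected ordering is clear (the mean
difference is positive at p < 10⁻⁶), but per-dataset orderings at this
locus count are unreliable; consistent Z > A across all 15 pairs of a real
survey is thus itself a noteworthy observation, not something a neutral
0.75-scaling model readily produces.

## Known limitations

* The HKA null simulator conditions on the fitted parameters (parametric
  bootstrap); for very small locus counts the test is mildly conservative.
* The AMOVA permutation schemes are the standard stratified ones; exact
  permutation distributions for the between-species level are coarse when
  few populations per species exist.
* The IM machinery is a simulator and unit converter, not an estimator: it
  generates data under given (theta, T, m) and converts scales, but does
  not compute posterior densities for them.
* Phasing is assumed done; chromatogram handling, statistical haplotype
  inference and sequence retrieval are out of scope.
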