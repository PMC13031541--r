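---
title: "Inversion karyotyping, diagnostic markers and arrangement-frequency clines: models and design decisions"
author: "KaryoCline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inversion karyotyping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KaryoCline)
```

# Overview

KaryoCline implements the computational chain used to detect and karyotype a
polymorphic chromosomal inversion from hard-called genotypes, to design a
diagnostic PCR-RFLP marker for it, to quantify latitudinal and thermal
clines of arrangement frequency, and to model karyotype-by-temperature
effects on egg-to-adult viability. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

# The inversion model

An inversion with two arrangements, S and N, suppresses recombination in
heterokaryotypes. Inside the inverted interval each chromosome copy belongs
to one arrangement background, so an individual's dosage at an
arrangement-differentiated site is determined by its karyotype (SS, SN or
NN). Two consequences drive everything downstream:

* a PCA restricted to the interval separates the three karyotypes along
  PC1, with heterokaryotypes in the middle and maximally heterozygous at
  arrangement-fixed sites;
* per-site differentiation between SS and NN homokaryotes is extreme
  (approaching FST = 1 at fixed sites) compared with the genomic
  background.

# Sliding-window scan and region calling

`windowPca()` computes, per window, the leading principal component of the
centered dosage matrix: dosages are centered at twice the site's allele
frequency, missing entries are mean-imputed (zero after centering), and an
optional `scale` argument divides by `sqrt(2p(1-p))`. Defaults:

* `windowSize = 50000` bp, non-overlapping (`step = windowSize`). 50 kb is
  small enough to resolve inversion boundaries at the sub-megabase scale
  and large enough to hold tens of SNPs at typical densities; the step is
  exposed for overlapping scans.
* `minSites = 10` usable polymorphic sites per window; windows below the
  threshold — including zero-variance windows — are flagged `skipped`
  rather than silently returning noise.
* Eigenvectors are sign-ambiguous, so each PC's sign is pinned by requiring
  a non-negative score for the lexicographically smallest sample ID. This
  makes results invariant to sample order.

`detectInversionRegion()` formalises what is usually done by eye. Per
window it fits 1-D k-means with k in {1, 2, 3} to the PC1 scores (20
restarts under a fixed sub-seed; best inertia wins, first found on ties)
and chooses k by BIC under an equal-variance Gaussian-mixture
approximation (parameter count 2k: k means, k-1 weights, one variance). A
window is *inversion-like* when k = 3 **and** the middle cluster's mean
heterozygosity over the window's sites exceeds both outer clusters'. The
heterozygosity condition is what distinguishes genuine karyotype
trimodality from, say, three geographic demes: heterokaryotypes must be
the most heterozygous group at sites differentiated between arrangements.
The call is the longest run of inversion-like windows tolerating at most
`gapMax = 1` non-qualifying windows, and the reported interval spans the
qualifying windows of that run. No inversion-like window yields an
explicitly empty call with full per-window diagnostics, never a forced
interval. A run-based rule is one of several defensible formalisations of
boundary restriction; the per-window diagnostics are always returned so a
user can audit or override the call.

`assignKaryotypes()` repeats the PCA on the called interval, k-means with
k = 3 on PC1, orders clusters by mean score and labels the middle one SN.
The outer clusters are oriented by anchor samples when supplied; otherwise
the outer cluster more frequent at the lowest-latitude location is called
SS, matching the convention that the S arrangement is the southern one.
If the SN cluster does not maximise mean heterozygosity the assignment is
flagged `low` confidence; fewer than three distinct PC1 values produce an
explicit failure state (a monomorphic arrangement cannot be forced into a
3-way split).

# Differentiation statistics

`hudsonFstSite()` implements Hudson's estimator (Bhatia et al. form) with
numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
`p1(1-p2) + p2(1-p1)`, where n1 and n2 are non-missing allele counts. The
numerator is unbiased, which has a visible consequence worth knowing:
comparing a group of n alleles with itself gives exactly -1/(n-1), not 0.
`windowedFst()` aggregates as a ratio of averages (sum of numerators over
sum of denominators) per 25-kb window and globally — never an average of
ratios, which would be dominated by low-information sites. Sites with
fewer than 4 non-missing alleles in either group, and sites monomorphic in
both, are excluded; empty windows report NA, not zero. This estimator was
chosen as the standard hard-genotype differentiation measure; it is not
numerically interchangeable with genotype-likelihood-based estimators, so
no equality with likelihood-based published values is claimed.

`pairwiseDivergence()` counts substitutions between aligned sequences.
IUPAC ambiguity codes compatible with the other base count as matches
(Sanger-corrected alignments are normally scored this way); positions with
N or a gap in either sequence are excluded and the pairwise alignment
length reduced accordingly. Percent divergence is reported to one decimal.

`minimumSpanningNetwork()` collapses identical sequences into weighted
nodes and returns, for ε = 0, the union of all minimum spanning trees:
distinct edge weights are processed in increasing order and, within a
weight class, every edge joining components that were distinct before the
class was opened is added. This is exact (tested against exhaustive
spanning-tree enumeration) and reduces to the unique MST when all pairwise
distances differ. ε > 0 generalisations are deliberately out of scope.

# Diagnostic PCR-RFLP marker design

`designMarkers()` composes three rules: the SNP must (1) lie in a CDS, (2)
be near-fixed between homokaryote groups (`minDiff = 0.99` on the
alternate-allele frequency difference, computed over non-missing calls),
and (3) be cut by a catalogue enzyme in exactly one allele. "Cut" requires
the recognition-site match to *overlap the SNP position* — a site elsewhere
in the window cuts both alleles and discriminates nothing. Both strands
are scanned; the enzyme catalogue stores a per-enzyme cut offset (EcoRI
G^AATTC has offset 1) because fragment-length prediction needs it, and
reverse-strand matches of non-palindromic sites are cut at the mirrored
offset. Amplicons default to 667 bp centred on the SNP (clipped at contig
edges); predicted patterns are: cut homokaryote = digest fragments, uncut
homokaryote = full amplicon, heterokaryote = the union. Candidates are
ranked by frequency difference, then by the minimum fragment-length
difference between the homokaryote patterns, with `gelResolution = 50` bp
as the usable threshold on a standard agarose gel. Primer thermodynamics
are out of scope; the amplicon sequence is emitted for external tools.
`concordance()` scores marker-vs-PCA agreement as an integer percent and
lists discordant samples individually, since discordance is where shared
polymorphism or gene conversion shows up.

# Clines and Hardy-Weinberg tests

`arrangementFrequency()` computes `p = (2 n_SS + n_SN) / (2 n)` with a
Wilson 95% interval on the allele scale. `hweTest()` compares observed
karyotype counts with `(n p^2, 2np(1-p), n(1-p)^2)` by plain chi-square,
df = 1, **without** continuity correction — the convention that reproduces
standard published karyotype-count tests; monomorphic locations are
flagged untestable rather than returning 0/0.

`fitBinomialCline()` fits `logit(p) = b0 + b1 x` by IRLS (`stats::glm`,
convergence at relative deviance change 1e-10 or 100 iterations) on the
*aggregated* binomial response (successes = 2 n_SS + n_SN, failures =
n_SN + 2 n_NN per location). Aggregation weights each location by its
sample size and gives estimates identical to a per-allele Bernoulli
coding; the likelihood-ratio chi-square is null minus residual deviance
(df = 1) and the fit measure is the deviance R² `1 - D_res/D_null`.
Quasi-complete separation is detected (fitted probabilities at the 0/1
boundary or implausibly large coefficients) and flagged with a warning
instead of being hidden. `predictCline()` builds the 95% ribbon on the
linear predictor (Wald) and maps it through the inverse logit, so the
interval is asymmetric near the boundaries and always contains the fit.

# Thermal performance curves

Viability is modelled as `v(T) = a T^2 + b T + c`. Because the model is
linear in its coefficients, ordinary (weighted) least squares on the
replicate-level proportions is the exact maximum-likelihood-for-Gaussian
solution, and multi-start nonlinear optimisation adds nothing; replicates
are weighted by eggs counted by default (`weights = "none"` switches to
unweighted). Derived traits are closed forms of the vertex and roots:
rmax = c - b²/(4a), Topt = -b/(2a), CTmin/CTmax the real roots, tolerance
their difference, and breadth `2 sqrt(0.2 rmax / (-a))` (the width where
v ≥ 0.8 rmax). Non-concave fits (a ≥ 0) and complex roots yield NA traits
with the fit still reported. A configurable exclusion rule
(`minMeanViability`, default 0.05 in the deviance analysis) drops
temperatures where almost nothing survives, since a handful of survivors
out of hundreds of eggs supports no stable proportion estimate.

`viabilityDevianceAnalysis()` fits the binomial GLM with all two-way
interactions of karyotype, temperature and continent (three-way and higher
interactions are excluded: with six replicates per cell they are
under-determined) and tests each term by an explicit type-II
likelihood-ratio model pair respecting marginality — a main effect is
tested in the model without its interactions. The implementation is pair
of nested `glm` fits per term, cross-checked in the test suite against an
independent type-II LR implementation.

# What the synthetic generators emulate

`simulateInversionDataset()` draws, per location, karyotypes from
Hardy-Weinberg proportions with `p_S = plogis(beta0 + beta1 * latitude)`;
outside the inversion, continent-specific allele frequencies come from a
Balding-Nichols model (Beta draws around a shared ancestral frequency with
parameter `fBg`), whose expected Hudson FST between continents is `fBg`
itself; inside the inversion a fraction `dInv` of sites is fixed between
arrangements, a fraction `muPoly` of the rest is polymorphic with equal
frequencies in both arrangements, and alleles are drawn per arrangement
copy with no recombination between backgrounds.

Default study conditions, chosen once: 6 locations spanning latitudes
48.7-68.4, 40 diploids per location alternating between two continents,
2000 sites on a 1-Mb chromosome with a 400-kb inversion, `fBg = 0.13`,
cline `beta0 = 6.23`, `beta1 = -0.11` per degree, `dInv = 0.3` and
`muPoly = 0.668`. The last value calibrates the analytic
between-arrangement FST target
`dInv / (dInv + (1 - dInv) * muPoly * E[2pq])` (with `E[2pq] = 0.3933`
for shared-polymorphism frequencies uniform on 0.1-0.9) to 0.62;
`targetArrangementFst()` exposes the formula. The viability generator's
default quadratic has its vertex at 20 °C with rmax = 0.26 and
zero-crossings near 9 and 31 °C, so that viability at 10 °C falls below
5% — the regime in which the exclusion rule engages.

What the generators deliberately do **not** emulate: linkage
disequilibrium within arrangements (sites are independent given the
arrangement, sufficient for PCA-cluster and FST structure but not for
haplotype-block statistics), coalescent genealogies and recombination
maps, selection dynamics, genotyping error, and within-arrangement
geographic substructure inside the inversion. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimators
and the calling logic under the assumed generative structure, not
robustness to every feature of real resequencing data.

# Numerical choices and degenerate inputs

* Coordinates are 1-based closed `GRanges` everywhere; VCF/GFF3 conversion
  happens at the boundary via VariantAnnotation/rtracklayer. A single
  convention package-wide prevents off-by-one drift.
* Multi-allelic and non-SNP VCF records are dropped (with a logged count),
  not split: the marker logic assumes biallelic SNPs.
* k-means uses 20 restarts under deterministic sub-seeds derived from a
  single user seed; every generator is bit-reproducible given its seed,
  and RNG state is restored after each call so library code never
  perturbs a user's stream.
* Sites with zero dosage variance (including the all-heterozygous case,
  whose allele frequency is 0.5 but which carries no PCA information) are
  excluded from PCA input.
* Monomorphic regions, all-one-karyotype samples, empty candidate sets,
  separation in the GLM, and non-concave TPC fits all produce explicit
  errors, failure states or NA-flagged traits — never silently plausible
  numbers.

# Problem sizes used in the test suite

The packaged validation uses 20 simulation seeds for region-recovery
(Jaccard >= 0.8 against truth), one default-scale dataset (240 samples,
2000 sites) for karyotype recovery and FST calibration, 200 replicate
cline simulations for confidence-interval coverage, brute-force oracles up
to 7 haplotypes for the network, and exhaustive grid searches for the TPC
traits. These sizes give stable pass/fail behaviour at interactive run
times while exercising every code path at the scale of the study design
they emulate.

# Known limitations

* Genotype likelihoods are not supported; the pipeline operates on hard
  genotypes, and low-coverage data should be genotyped upstream.
* Only one inversion is called per chromosome scan (the longest qualifying
  run); overlapping or nested polymorphisms need manual window inspection.
* The ε = 0 network is exact but quadratic-to-cubic in unique haplotypes;
  it is intended for marker-region alignments, not genome-scale sets.
* The concordance report identifies discordant individuals but does not
  infer the mechanism (gene conversion vs technical failure); the local
  re-genotyping that distinguishes these is left to the user.
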