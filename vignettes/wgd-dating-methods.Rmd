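---
title: "Methods: synonymous-substitution clocks for WGD and TE dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synonymous-substitution clocks for WGD and TE dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdclock)
```

## The problem

Polyploid plant genomes carry the scars of whole-genome duplications
(WGDs) as clusters of paralogous gene pairs that all began diverging at
the same moment. Because synonymous substitutions are close to neutral,
the synonymous divergence Ks of such a pair acts as a clock: a WGD
appears as a peak in the distribution of Ks across syntenic paralog
pairs, and an independently dated event shared across lineages lets
those peaks be converted into absolute ages. wgdclock implements that
whole chain — pairwise Ka/Ks, block-median Ks distributions, mixture
peaks, rate-corrected dating — together with the two companion clocks
commonly reported alongside it: LTR retrotransposon insertion times from
5'/3' LTR divergence, and a per-GO-category binomial test for lineages
with accelerated protein evolution, plus an intact-versus-fragmentary
TE proximity analysis.

## Ka/Ks by Nei–Gojobori counting

`kaks_pair()` implements the NG86 counting estimator. Each codon
contributes fractional synonymous site counts: of its nine single-base
mutants, the fraction that preserve the encoded amino acid (mutations
that create a stop codon count as nonsynonymous sites). Sites are
averaged over the two sequences. Differences between a codon pair are
averaged over all minimal mutational pathways (1, 2 or 6 orderings of
the differing positions) with equal weights; pathways that transit a
stop codon are excluded, and in the rare case that every pathway
transits a stop, the stop-transit pathways are retained and the pair is
flagged. The difference proportions `pn = Nd/N` and `ps = Sd/S` are
corrected for multiple hits with the Jukes–Cantor transform
`d = -(3/4) log(1 - 4p/3)`.

Numerical conventions:

* Codon pairs containing a gap, an `N`, any ambiguity, or a stop codon
  are skipped pairwise, not column-masked globally. This keeps the
  estimator local to each pair; on clean alignments it is a no-op.
* `p >= 0.75` is substitution saturation: the estimate is reported as
  missing with a `*_saturated` flag, never as a number.
* `omega = ka/ks` is only defined when `ks > 0`; otherwise it is `NA`
  with an `omega_undefined` flag rather than an error, since identical
  pairs are legitimate inputs.
* Pathway weighting is uniform (no transition/transversion weighting),
  matching the plain NG86 variant.

One subtlety worth knowing: even under a purely synonymous substitution
process, NG86 can assign small fractional nonsynonymous differences.
When the two lineages take synonymous steps into different codon boxes
of a split amino-acid family (e.g. arginine CGA→AGA in one copy and
CGA→CGC in the other), the minimal pathways between the resulting
codons pass through other amino acids and pathway averaging splits the
difference. Tests therefore assert `ka ≈ 0`, not `ka = 0`, for
synonymous-only simulations.

## Block-median Ks distributions

Collinearity anchors (from MCScanX-class tools, or the built-in
simulator) are grouped into syntenic blocks; `block_median_ks()`
summarises each block by the median Ks of its usable pairs. A pair is
usable when its Ks is present (not saturated), positive, and at most
`ks_max` (default 5.0 — the upper plotting bound is a package choice,
as practice varies). Blocks are retained only when they have at least
`min_pairs = 10` usable pairs, the conventional "at least 10 collinear
genes" filter; the usability filter runs *before* the size filter so
that saturated pairs cannot rescue thin blocks. Medians of blocks, not
raw pairs, are fitted downstream: block medians are far less dispersed
than single-pair Ks and make each WGD cohort approximately Gaussian.

## Mixture peaks by EM

`fit_ks_peaks()` fits a finite Gaussian mixture to the block medians by
expectation–maximisation within a window (default `(0, 3]`; fitting on
raw Ks is the default because block medians are already unimodal per
event, with log-space fitting available via `log_scale = TRUE`).
Numerical choices:

* Initialisation is multi-start: a k-means solution, a quantile-spread
  start, and random draws (10 starts in total, seeded). Every start is
  run briefly at coarse tolerance and the best by log-likelihood is
  polished to a relative log-likelihood change below `1e-8` (at most
  2,000 iterations). Multi-start matters here: with two narrow peaks
  close together next to one broad peak, a single k-means start
  reliably finds a merged local optimum.
* The log-likelihood is asserted non-decreasing at every iteration; a
  decrease aborts the fit rather than silently returning it.
* A component whose variance collapses (sd below 1e-6) or that starves
  (fewer than two expected members) invalidates the start; if every
  start for a given k degenerates, the model is refit at k−1 and
  flagged `component_pruned`.
* `k = "auto"` selects the component count in 1..5 by lowest BIC.

Peak-position uncertainties come from `bootstrap_peak_se()`: a
nonparametric bootstrap (default 200 replicates) refits the mixture on
resampled values and reports the standard deviation of each component
mean. Replicate components are matched to the full-sample components by
minimal total absolute mean difference over all permutations (exact for
k ≤ 6), which prevents label switching from corrupting the SEs. The
"±" convention on published peak positions is rarely stated; this
bootstrap is the package's own documented convention, not a
reconstruction of anyone else's.

## Rate correction and absolute dating

Lineages evolve at different rates, so the same ancient event sits at
different Ks in different genomes. With the core-eudicot common
hexaploidization (ECH, the γ whole-genome triplication, ~115–130 Ma) as
the shared anchor, `relative_rate()` computes the focal lineage's
relative rate `r = (kH − kV)/kV` from the focal (`kH`) and reference
(`kV`) within-genome ECH peaks, and the correction coefficient
`WH = 1/(1 + r)`, so that `WH·kH = kV` exactly; between-genome ortholog
peaks are corrected as `WH·kH−V` by `correct_ks()`.

`date_peaks()` converts a within-genome peak into an age as
`T = (peak_ks / kH) · T_cal`, evaluated at both calibration bounds so
each event is reported as an interval, mirroring how such ages are
printed. This closed form is algebraically identical to
correct-then-divide-by-reference-rate, and the reference peak cancels —
a property asserted to 1e-12 in the tests, which is why the function
does not require a reference genome at all. Peaks larger than the
calibration peak are dated anyway but flagged `predates_calibration`.
Per-lineage substitution rates come from `substitution_rate()`,
`rate = K/(2T)` with T in years (the factor 2 because both copies
accumulate substitutions). The published per-species rates derived this
way are not mutually consistent with every printed peak/interval
combination (they imply a calibration time near 143 Ma given an ECH
peak of 2.019), so the calibration time is exposed as a free parameter
rather than reconciled. Where a source says the LTR rate is "per
generation", the package treats rates uniformly as per year; for a
woody perennial the distinction matters and is a documented
approximation, not a claim.

Ages are reported in Ma with an explicit 1e6 factor and rounded to one
decimal only at the reporting layer.

## LTR insertion times

The two LTRs of a retroelement are identical upon insertion;
`ltr_divergence()` measures their present-day divergence over
comparable columns (both bases unambiguous; at least 50 such columns,
below which the pair is flagged) and corrects it under JC69 (default)
or K2P. JC69 is the default because the model behind published
insertion ages is often unstated; K2P — the convention of
LTR_retriever-class tools — is a switch recorded in output metadata.
`insertion_time()` inverts the clock as `T = K/(2μ)`, and
`insertion_time_profile()` bins ages (default 0.1 Ma) overall and per
superfamily, reporting mode, mean and median — all three, because
"the burst was at ~1 Ma" claims rarely say which statistic they mean.

## GO-category acceleration test

For each lineage, per-ortholog NG86 difference counts against a common
outgroup are pooled: the genome-wide nonsynonymous fraction
`p = Σn/(Σn + Σs)` is the null. Each GO category with more than 20
member orthologs is tested with the one-sided exact binomial tail
`P[X ≥ a]`, `X ~ Binomial(a + s, p)`, where `a` and `s` are the
category's summed nonsynonymous and synonymous differences. Categories
at or below 20 members are reported untested; categories with zero
substitutions are flagged untestable. Pathway-averaged counts are
fractional, so category totals are rounded to the nearest integer for
the exact test — at category sizes where the test is applied (hundreds
of substitutions) this changes tail probabilities negligibly. The
pooled (not per-ortholog) expectation is the package's documented
reading of the consortium-style construction this test descends from.
No multiple-testing correction is applied to the primary p-values,
matching the raw `P < 0.05` reporting convention; a Benjamini–Hochberg
column is always emitted alongside. `two_lineage_contrast()` labels
each category accelerated-in-focal/-other/both/neither, requiring
identical GO universes. A gene counts toward every category it is
annotated to; GO-graph ancestor propagation is deliberately out of
scope.

## TE proximity to genes

`nearest_gene_distance()` computes, for every TE interval, the gap in
bp to the nearest gene on the same chromosome (0 on overlap or
adjacency), on 0-based half-open coordinates with strand ignored —
the convention of standard interval toolkits, since "distance" is
rarely defined in figure captions. The implementation delegates to
GenomicRanges; the test suite checks it exactly against an all-pairs
brute-force scan and under coordinate reversal. `proximity_test()`
compares intact against fragmentary elements with a chi-square test on
the 2×2 table of status × (within / beyond 1 kb of a gene) — the 1 kb
bin edge is a configurable package choice, as published chi-square
binnings are unstated — without continuity correction so the nominal
level is honest at these group sizes, and always accompanies it with a
Wilcoxon rank-sum test on the raw distances plus the direction of the
difference by group medians.

## The synthetic-data generator

Every input has a seeded generator, so the full pipeline runs and is
tested without any genome download:

* `simulate_gene_pairs()` evolves both copies of a random stop-free
  ancestral CDS by Poisson-distributed single-base proposals (expected
  pairwise synonymous divergence = `target_ks`), accepting synonymous
  proposals always, nonsynonymous ones with probability ω, and
  stop-creating ones never. This per-column Bernoulli/Poisson process
  is an approximation to a full continuous-time codon model: with
  uniform ancestral codon frequencies it makes NG86's site counts
  unbiased by construction, recovers Ks to within a few percent at
  Ks ≤ 1, and biases Ks slightly low above Ks ≈ 2.
* `simulate_ks_mixture()` / `simulate_synteny()` draw block medians
  (and per-block anchor pairs) from Gaussian WGD cohorts; the default
  cohorts sit at Ks 0.329, 0.502 and 2.019 with sds 0.04/0.06/0.25 and
  weights 0.35/0.35/0.30 — the configuration of a genome with two
  recent tetraploidizations on top of the eudicot hexaploidy. A tenth
  of blocks are emitted below the 10-pair threshold to exercise the
  filter.
* `simulate_ltr_pairs()` evolves both LTR copies per column under the
  exact JC69 transition kernel for `μ·T` per branch (default cohort:
  500 elements, 1 kb, 1 Ma at μ = 7.06e-9 per site per year).
* `simulate_annotations()` places genes on a jittered grid (which
  guarantees non-overlap) and drops intact TEs within 500 bp of a
  random gene with probability `near_gene_fraction` (default 0.8,
  fragmentary TEs uniform), a deliberately strong planted signal for
  power checks; setting both fractions equal yields the null layout
  used for calibration.
* `simulate_ortholog_counts()` simulates the acceleration test's
  inputs at the count level (Poisson substitutions per ortholog,
  binomial nonsynonymous share, 3× rate enrichment in planted
  categories), which is the right granularity for type-I/power
  calibration at thousands of categories.

What the generator does **not** emulate: indels and alignment error,
codon-usage and GC bias, rate variation across sites and genes,
segmental (non-whole-genome) duplication contaminating Ks
distributions, nested/truncated TE structures, and gene conversion
between LTRs (which in real data pushes insertion ages toward zero).
Passing recovery tests on these synthetics therefore demonstrates
estimator correctness, not robustness to those real-data artefacts.

## Problem sizes and determinism

All stochastic functions take explicit integer seeds (default
20221214) and are byte-reproducible given seed and config. The test
suite runs, among others: oracle equivalence on 1,000 random 300-codon
pairs at 1e-12; mixture recovery on 2,000 block medians; BIC model
selection over 50 replicate datasets of 400 values at ≥ 4-sd
separation; bootstrap-vs-Monte-Carlo SE comparison at 100 replicates
each; binomial-test calibration on 2,000 null categories of 50
orthologs and power on 10 planted categories; TE proximity null
calibration over 1,000 replicate draws of 500 + 500 distances. These
sizes are the package's chosen balance between Monte-Carlo error and a
test suite that stays pleasant to run.

## Known limitations

* NG86 with Jukes–Cantor correction underestimates divergence when
  transition/transversion bias or codon-usage bias is strong; the
  YN-style ML estimators are out of scope by design.
* EM on raw Ks assumes roughly Gaussian cohorts; heavily skewed
  single-pair Ks distributions should be summarised to block medians
  (as intended) or fitted in log space.
* The binomial acceleration test inherits the usual caveat that GO
  categories overlap and genes are not independent; its p-values rank
  candidates rather than certify them.
* Dating accuracy is bounded by the calibration interval's width and
  by the assumption of rate constancy within each lineage after
  correction.
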