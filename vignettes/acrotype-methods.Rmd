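---
title: "Methods: cohort subtyping of acral melanoma"
author: "acrotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort subtyping of acral melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrotype)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, and the choices made where the
design was genuinely open.

# Variant consensus

Somatic calls from three callers are merged by site identity after a
prefix-then-suffix trimming of redundant indel representations (full
left-alignment would require the reference sequence; trimming reconciles
the common left-/right-anchored deletion encodings and is applied
identically to all callers, so matching is consistent). A site is kept
when at least two callers support it; a gene + HGVS protein-change rescue
list (default `BRAF:p.V600E`) retains well-established oncogenic variants
on single-caller support. Rescue matching uses the normalized protein
change, not coordinates, so it survives transcript-version differences
between annotation pipelines. Base-quality filtering keeps Phred ≥ 30
(inclusive); records lacking quality or strand-bias annotations are not
penalized, since not every caller emits them. One sample per patient is
selected with primaries preferred, then earlier collection date, then
lexicographic sample id — a fully deterministic order. TMB is (SNVs +
indels) / capture size, default 50 Mb, in mutations per megabase.

# Copy number

Purity/ploidy QC compares two independent purity estimates: a sample
fails on absolute discrepancy (> 0.5 by default), on the
extreme-disagreement pattern (one estimate < 0.15 while the other
≥ 0.95), or on goodness of fit < 95 (equality passes). Missing estimates
yield a distinct `unassessable` status rather than a silent pass.

Segment values are ploidy-normalized: `segMean = log2(cn/ψ)`, with
`cn = 0` capped at −5 (a finite stand-in for −∞ that stays below every
realistic threshold). Region values are classified with the conventional
GISTIC-style cuts (neutral within ±0.25, high-level amplification above
0.9, high-level deletion below −1.3); the boundary values 0.9 and −1.3
fall in the low-level classes so the classes partition the line.

The burden scores are: BCS = Σ over arms of |length-weighted mean
segMean| for arms whose |mean| exceeds 0.2 (chosen below the 0.25
low-amplification cut so that genuine arm events are never excluded by
the burden threshold); FCS = Σ over sub-arm segments (covering < 90% of
their arm) of |segMean| × length/armLength; each component min–max
normalized to [0, 50] across the cohort and summed into GCS ∈ [0, 100].
The upstream tool's exact normalization is unpublished, so GCS here is a
cohort-relative quantity: orderings and correlations are meaningful,
absolute values are not comparable across cohorts, and a cohort of one
sample is an error rather than a degenerate normalization.

Homozygous deletions are called from bin-level log2 ratios against the
sample-specific expectation for tumour copy number zero,
`log2(2(1−ρ)/(ρψ + 2(1−ρ)))` (−5 at ρ = 1): only normal cells contribute
DNA at such a locus. The large-gene rule requires two contiguous in-gene
bins at or below the threshold, or one whole exon with zero coverage.
The small-gene rule — replacing a manual-scrutiny step that is not
reproducible — requires one bin at/below threshold, two further bins
within 0.3 of it, and an in-gene mean at least 0.5 below the flanking
mean. Because focal deletions commonly extend beyond a small gene's
footprint, the 6 bins adjacent to the gene are skipped before the 5
comparison bins are taken on each side; without this gap, partially
deleted neighbour bins mask the contrast. Bins are 0-based half-open
(BED convention), segments 1-based inclusive (SEG convention).

# The melanocytic-origin (A:C) score

Counting-panel data are normalized by housekeeping geometric means: each
sample is scaled by reference/geomean(sample), where the reference is the
geometric mean of the per-sample geometric means (this choice — rather
than the arithmetic mean — makes a 3-sample cohort with geomeans 10/20/40
scale by exactly 2/1/0.5). Scaled counts are floored at the background
threshold 20 and log2-transformed, so every value entering the score
exceeds log2 20 ≈ 4.32 and products are positive. A fixed reference can
be supplied to score new samples against a training cohort; under a
fixed reference a sample-wide multiplicative factor cancels exactly.

The panel is trained by PCA with samples as observations and genes as
variables (column-centred, unscaled). Rather than hard-coding the second
component, the component whose scores correlate most strongly (point
biserial) with the acral/cutaneous label is selected and its index
recorded; on training data where a dominant technical axis occupies the
first component, the label-associated component is indeed the second,
which the suite asserts on such a fixture. The top and bottom ten genes
by loading form the two sides, oriented so acral samples score high.

The score is multiplicative: the product of the acral-side log2 values
over the product of the cutaneous-side values. The reading "product of
log2 values" (rather than product of raw expressions) is adopted; the
group-ordering properties used by every comparison hold under either
reading. With equal panel sides the score is invariant to a common
multiplicative factor on the log2 values; the log-score (difference of
sums of log2(log2 expr)) is exposed for numerical stability. RNA-seq
input is normalized by median-of-ratios size factors, log2(x+1), with
optional per-batch gene centring, floored at 1 + 2⁻¹⁰ so the log2 values
stay above 1.

Group comparisons use the Wilcoxon–Mann–Whitney test; the one-sided
direction for BRAF-status comparisons is "BRAF-activating scores lower
on the A:C scale", asserted only on synthetic data where the direction
is planted.

# Consensus clustering and signatures

Preprocessing applies, in order: removal of rows with more than 25% NA
(exactly 25% is kept), row-median imputation of the rest, per-row
winsorization at the 5th/95th percentiles (type-7 quantiles, the R
default), removal of zero-variance rows, and removal of rows below the
5th variance percentile. Row-median imputation was chosen as the
simplest imputation that cannot leak cluster structure.

Consensus partitioning subsamples 80% of samples 50 times per candidate
k (defaults; tests and the acceptance battery use 25–30 resamples at
their smaller sizes), clusters each subsample (kmeans, pam or hclust/
Ward on Euclidean distance, over the top 2,000 features by sd, mad or
cv), and accumulates consensus(i,j) = co-clustered / co-sampled counts.
Final labels cut the average-linkage tree of 1 − consensus. PAC is the
fraction of off-diagonal consensus entries strictly inside (0.1, 0.9) —
interval bounds are a documented default, as the framework that inspired
them does not publish one; concordance is the mean pair-level agreement
of each resample partition with the final labels; the Jaccard index
compares co-clustered pair sets at k and k − 1; mean silhouette is
computed on the 1 − consensus distance. The chosen k (and, in the grid,
the feature:method pair) maximizes 1-PAC with exact ties broken by mean
silhouette. A "largest stable k" rule was considered and rejected:
forced splits of tight clusters can look deceptively stable under
subsampling, so the rule over-partitions planted data.

Signature genes come from per-gene one-way fixed-effects F-tests across
the final clusters with BH adjustment (q < 0.05); constant genes get
F = 0, p = 1. Significant genes are assigned to their argmax-mean
cluster, then grouped into modules by k-means (k = 3, 25 restarts, fixed
seed) on row-standardized cluster-mean profiles; modules are labelled by
peak cluster, with size breaking ties, so naming is stable under gene
permutation. Over-representation uses the upper-tail hypergeometric
probability including the observed overlap, BH-corrected across sets.

# Statistical inference

All tests the pipeline relies on are implemented in the package and each
is checked against an independent oracle in the suite:

- Pearson χ² without continuity correction — the only variant that
  reproduces the reference contingency p values (0.007 / 0.042 / 0.017)
  from tables reconstructed from printed percentages and group sizes.
- Fisher's exact 2×2 test with the probability-mass two-sided rule and
  the conditional-MLE odds ratio; the Freeman–Halton r×c generalization
  enumerates the margin-constrained lattice exhaustively, guarded at a
  table total of 200 beyond which a Monte-Carlo variant is advised.
- Mann–Whitney U with midranks; exact p by the classical count recurrence
  when both groups have ≤ 12 observations and no ties (a desk-scale
  enumeration bound), otherwise a normal approximation with tie and
  continuity corrections. Fully tied data return p = 1.
- Logistic regression by IRLS (score tolerance 1e-8, 50 iterations, step
  damping), Wald intervals; separation is detected (diverging
  coefficients with fitted probabilities at 0/1) and flagged, not
  "corrected" — Firth-type penalties are out of scope.
- Kaplan–Meier with Greenwood variance and log-log 95% bands (NA at
  S = 0 where the transform is undefined); log-rank with hypergeometric
  variance; Cox partial likelihood with Efron ties (Breslow by flag),
  Newton–Raphson with step-halving, and optional delayed entry via
  (entry, time] risk sets for recruitment-lag analyses.

Wald (not profile) intervals are used throughout, matching the symmetric
on-log-scale intervals the reported cohort results carry.

# The synthetic cohort generator

The generator's defaults are the study conditions the analyses assume:

- **Ancestry**: Dirichlet with concentrations (7.880, 1.585, 0.507),
  solved numerically so the component medians are 81% Amerindian, 13.6%
  European, 2.5% African.
- **Drivers**: multinomial logit with QWT reference; intercepts
  (−2.0703, −2.0703, −2.5698, −2.5121) calibrated by Monte-Carlo fixed
  point to marginal frequencies NRAS 14%, KIT 14%, BRAF 13%, NF1 9%
  under the planted female log-odds log 3.83 (all genes) and
  European-ancestry log-odds 2.5 (BRAF only). A single categorical draw
  enforces mutual exclusivity; a multi-hit flag (rate 1/92) adds a
  second driver.
- **Expression**: negative binomial, log2 mean = baseline 5 + lineage
  effect 3 (v-type genes in acral, c-type in cutaneous) + cluster-module
  effect 2 (three 40-gene modules with cluster probabilities 14:16:14) +
  log-uniform library factor in [0.5, 2]; dispersion 0.15; BRAF-flagged
  acral samples shift 2 log2 units from the v- to the c-type program.
  Dispersion 0 disables sampling and returns exact means — the
  deterministic limit used by separation and invariance tests.
- **Variants**: passenger count Poisson with mean 0.95/Mb over 50 Mb,
  modulated by a per-patient latent intensity (log-sd 0.6, mean
  preserved); driver variants carry gene and protein-change annotations;
  by default all three callers see every variant (the no-noise setting
  under which consensus must reproduce planted labels exactly).
- **Copy number**: purity uniform on [0.4, 0.95] (the QC-passing range),
  ploidy 2 with a 23% whole-genome-duplication rate (ploidy 4), per-arm
  event odds coupled to the same latent intensity (coefficient 1.4, base
  rate 0.12) — the coupling constants were calibrated at large n so the
  realized GCS–TMB Pearson correlation is ≈ 0.72; focal events at rate 2
  per genome; homozygous deletions planted at CDKN2A-like (25%) and
  NF1-like (5%) loci; bins of 20 kb over gene ± 1 Mb with Gaussian noise
  σ = 0.15 on the mixture-model log2 ratio.
- **Outcomes**: recurrence logistic with intercept logit(0.372) (the QWT
  recurrence rate), driver log-odds log 5.31, small stage and age
  effects; death exponential with baseline hazard 0.035/yr, driver
  log-hazard log 3.19, administrative censoring at 10 years; recruitment
  lag exponential with mean 2.01 years, truncated below follow-up.
  Left-truncation correction is off by default; the Cox implementation
  accepts delayed entry for sensitivity analyses.

One master seed drives everything through the child-seed scheme
`(seed·48271 + 1000003·index) mod (2³¹−1)`, so identical (config, seed)
pairs reproduce cohorts byte-identically and components can be
re-simulated independently.

What the generator does **not** emulate: read-level data, mutational
signature spectra, germline genotypes, immune-cell composition,
FFPE-specific artefact structure, and the correlated missingness of real
clinical tables. Passing recovery tests therefore shows that the
implementations are correct under the stated generative model — not that
real cohorts of this size would yield the same power or calibration.

# Problem sizes and runtime choices

The test suite exercises cohorts of 15–150 patients, exact-test oracle
sweeps over all 2×2 tables with total ≤ 12 and all rank-test pairs up to
6 + 6, coverage experiments of 100 replicates at n = 400–600, and the
44-sample clustering grid with 30 resamples — sizes chosen so the whole
suite runs in a few minutes on one CPU while keeping Monte-Carlo error
well inside the asserted bands. The acceptance battery averages
recurrence/hazard recovery over five cohorts of 2,000 and TMB over four
cohorts of 123 so that reported values sit within ~2 standard errors of
the planted quantities.

# Known limitations

- GCS absolute values are cohort-relative by construction; only ordering
  and correlation claims are made or tested.
- The large-gene homozygous-deletion rule loses sensitivity when a gene
  spans few bins; at the default 20 kb bins an NF1-sized gene spans ~20
  bins and the rule performs well, but coarse binning degrades it.
- The exact r×c test enumerates exhaustively and is guarded, not
  approximated, beyond a table total of 200.
- Separation in logistic models and monotone likelihood in Cox models
  are flagged, not penalized.
- The multinomial-logit driver model makes per-gene logistic fits an
  approximation at high driver prevalence; at the planted frequencies
  the attenuation is negligible relative to sampling error, which the
  coverage experiments quantify.
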