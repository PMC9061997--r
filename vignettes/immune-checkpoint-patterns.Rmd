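---
title: "Immune checkpoint regulation patterns and the ICscore: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune checkpoint regulation patterns and the ICscore: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpattern)
```

## The problem

Immune checkpoint molecules — costimulatory and coinhibitory ligand/receptor
pairs such as PD-1/PD-L1, CTLA4, CD27/CD70 — act in a coordinated way, and
tumors differ in how the whole panel is regulated rather than in any single
gene. `icpattern` implements a cohort-level analysis of that coordination
for gastric-cancer-like expression cohorts: it discovers *checkpoint
regulation patterns* by consensus clustering samples over a fixed 31-gene
panel, derives pattern-associated signature genes, condenses them into a
per-sample *ICscore*, and relates the score to immune infiltration,
survival, tumor mutation burden (TMB) and clinical subtypes.

The package ships a synthetic-cohort generator with the full linked
structure the analysis assumes, so every stage is exercised end to end
without any external download.

## The 31-gene panel

`load_icg_registry()` returns the fixed panel: 12 costimulatory and 19
coinhibitory molecules, of which 17 are ligands and 14 receptors. The
composition is asserted at load time; clustering only ever uses the panel
rows present in the input matrix.

## Pipeline stages and their models

### Batch correction

Multi-cohort integration is modeled as per-(gene, batch) additive location
and multiplicative scale effects on log2 expression — the classical
two-moment empirical-Bayes batch model. `combat_adjust()` standardizes each
gene against the batch-size-weighted grand mean and pooled residual
variance, estimates per-batch location/scale parameters, shrinks them
toward parametric priors (normal for location, inverse-gamma for scale;
method-of-moments hyperparameters, fixed-point iteration to relative
tolerance 1e-4, at most 100 iterations), and removes them. With
`parametric = FALSE` the raw estimates are used; combined with
`mode = "location_only"` this equalizes per-gene batch means exactly, which
is the property the unit tests pin down. Scale adjustment contracts
residuals by an O(1/n) degrees-of-freedom factor per pass (the reference
convention), so exact idempotence holds only for location adjustment; a
second full pass moves the data by well under the original batch effect.
Genes without within-batch variance are returned untouched and flagged.
No covariates are preserved: the integration step is deliberately
unsupervised.

### Pattern discovery

`consensus_cluster()` subsamples 80% of samples 1000 times (both
config-exposed), partitions each subsample with PAM (k-medoids), and
records for each sample pair the fraction of co-sampled runs in which it
co-clustered. Final labels cut an average-linkage tree of one minus the
consensus matrix.

**Distance choice.** The default dissimilarity is Euclidean distance on
gene-standardized values, not 1 − Pearson profile correlation. The reason
is geometric: checkpoint patterns differ mainly by a panel-wide
up/down-shift, and profile correlation centers each sample's 31-gene
profile, discarding exactly that shared component; moreover a correlation
estimated from 31 points has a standard error near 0.2, so pairwise
dissimilarities become noise-dominated at panel size. On cohorts with
planted patterns the Euclidean form recovers them essentially perfectly
while the correlation form plateaus around ARI 0.4–0.5 regardless of
resampling effort. `dist = "pearson"` remains available for inputs where
profile shape, not level, is the signal of interest.

The number of patterns is chosen by the *proportion of ambiguous
clustering* (PAC): for each k, the empirical CDF of off-diagonal consensus
entries is evaluated at the ambiguity interval (0.1, 0.9) and
PAC = F(0.9) − F(0.1); the k minimizing PAC wins, ties toward smaller k.
The relative change in area under the CDF (delta-area) is reported
alongside. A forced k is accepted for both clustering passes (the
checkpoint pass typically selects k = 3; the signature-gene pass is run at
k = 2).

Cluster labels are canonicalized to A, B, C in decreasing order of mean
panel expression, so "A" is always the immune-hot pattern and labels are
comparable across runs and seeds.

### Single-sample enrichment

`ssgsea()` scores a gene set in one sample by ranking that sample's genes
(average ranks on ties) and walking them in decreasing order; the score is
the summed difference between the weighted in-set cumulative fraction
(weights rank^alpha, normalized) and the uniform out-of-set cumulative
fraction. `alpha = 0.25` is the conventional weight and is config-exposed.
Scores depend only on within-sample ranks, hence are invariant to any
strictly monotone transform of a sample's values — a property the tests
assert metamorphically. If a set covers every matrix gene, the out-of-set
step is empty and the score is the in-set walk alone. ESTIMATE-style
analysis uses the same walk on a stromal and an immune signature, with the
combined score defined as their exact sum. The published 141-gene ESTIMATE
signatures are not bundled (their versioning is ambiguous); signatures are
inputs, and the synthetic generator emits its own. Spearman correlation is
Pearson on average ranks with a t-approximation p; distance correlation
double-centers Euclidean distance matrices and takes a seeded permutation
p (999 permutations by default).

### Signature derivation and the ICscore

Differentially expressed genes are computed per unordered pattern pair
with a Welch t test on log expression (Wilcoxon optional) and BH
adjustment within each contrast; the signature is the *intersection* of
the significant sets at adjusted p < 0.05. Moderated-variance modeling is
deliberately not reimplemented: the pipeline's contract is the
intersection-and-score procedure, and at the cohort sizes involved the
Welch test is an adequate stand-in.

`derive_icscore()` z-scores the signature genes, fits a PCA over samples,
and defines each sample's score as the sum of its first two component
coordinates. Summing per-gene contributions (loading × standardized
expression) over signature genes telescopes to exactly this quantity, and
the tests assert the identity against a brute-force eigensolver. PCA signs
are arbitrary, so each component is oriented to make its loading sum
non-positive; higher mean signature expression therefore drives the score
*down*, fixing "low ICscore = immune-hot" across runs. Genes are z-scored
before the PCA and no univariate prognostic pre-filter is applied; both
choices are config-visible behaviors of the function surface rather than
hidden switches.

The score is dichotomized at the maximally selected log-rank cutpoint:
candidates are midpoints between consecutive sorted unique scores whose
induced groups each hold at least `minprop = 0.1` of samples; the chosen
cutpoint maximizes the absolute standardized two-group log-rank statistic,
ties resolved toward the median. An exhaustive scan is the test oracle.

### Survival and genomics statistics

Kaplan–Meier, log-rank and Cox fits are delegated to the `survival`
package behind thin, contract-fixing wrappers: Efron tie handling by
default (Breslow optional; both agree exactly on tie-free data, which is
tested), Newton–Raphson convergence at relative tolerance 1e-9 with at
most 50 iterations, Wald 95% intervals, constant/collinear covariates
rejected before fitting, and |beta| > 20 flagged as separation. The
univariate screen reports, per gene, a continuous-expression Cox fit and a
median-split log-rank p, labeling genes favorable/poor by the sign of
beta.

Contingency analysis uses the two-sided Fisher exact test
(point-probability method — tables no more probable than the observed one
are summed) for 2×2 tables and Pearson chi-squared otherwise; odds ratios
are sample ORs with the Haldane–Anscombe 0.5 correction on zero cells,
while exact p-values always come from the uncorrected table. TMB is a raw
nonsynonymous record count per sample (missense, nonsense, frameshifts,
in-frame indels, splice site, translation start, nonstop) — the capture
size needed for a per-megabase rate is an explicit argument, never
assumed. Mutation co-occurrence tests every gene pair by Fisher exact with
BH across all pairs. CNV input is collapsed to gain/neutral/loss because
only gain/loss frequencies are consumed.

## What the synthetic generator emulates

One latent "immune-hot" axis per sample (normal around +1/0/−1 for
patterns A/B/C, sd 0.5) links all data types:

* **Panel expression**: each of the 31 genes gets a discrete per-pattern
  mean shift of ±`icg_effect` (default 1.5 log2 units) with a per-gene
  magnitude drawn once from Unif(1/3, 5/3) × `icg_effect` — genes differ
  in dynamic range, while the panel-mean gap stays at the configured
  value. Two genes (defaults CD276, VTCN1) are reversed, mirroring the
  known exceptions in the hot pattern.
* **Background genes**: 2000, of which 300 respond to the axis (±0.8 log2
  per axis unit) — these are the recoverable signature genes; the rest are
  null.
* **Immune-cell sets**: 28 sets of 30 genes; most respond positively to
  the axis (Unif(0.6, 1.2) per axis unit), a minority (default 4) are flat
  or slightly negative so that "most sets up in the hot pattern" is a real
  majority rather than unanimity. Two 50-gene signatures (immune: effect
  1.0; stromal: 0.25) feed the ESTIMATE-style scores — the weak stromal
  effect mirrors the much smaller stromal than immune contrast between
  hot and intermediate patterns.
* **Batches**: 3, with additive location (sd 0.5) and multiplicative scale
  (log-sd 0.15) per gene — exactly the family the corrector models, so
  correction is identifiable.
* **Survival**: exponential event times with baseline rate 0.008 per month
  (baseline 5-year survival ≈ 0.6, the scale such cohorts show) and log
  hazard −log(2) per standard deviation of the axis: immune-hot is
  protective. Censoring is independent Uniform(0, b), with b solved so the
  marginal censored fraction hits the configured 30%.
* **Mutations**: per-sample Poisson background load with mean
  8 × exp(0.4 × axis) spread over a 97-gene panel plus three focal genes
  (ARID1A/PIK3CA/TP53 stand-ins) with pattern-dependent hit probabilities
  (ARID1A 55%/35%/15% for A/B/C, PIK3CA 40%/25%/10%, TP53 35%/40%/45%),
  plus Poisson "Silent" records to exercise the nonsynonymous filter. TMB
  therefore rises with the immune axis and falls with the ICscore.
* **Clinical subtypes**: MSI-like, stage, N stage and recurrence are
  multinomial with pattern-dependent proportions (MSI-H enriched in A).
* **CNV**: independent per-gene gain/loss calls over the panel with
  gain-prone and loss-prone genes fixed to the reported directions.

Everything is a pure function of the config and its seed; the pipeline
derives per-stage seeds from one global seed through a fixed name table,
so adding a stage never perturbs earlier stages' draws.

**What it does not emulate**: real marginal expression distributions,
gene–gene correlation beyond the planted blocks, platform-specific probe
effects, informative censoring, subclonal mutation structure, or
copy-number/expression coupling. Passing tests demonstrate that the
machinery recovers known structure under the stated model — not that the
biological conclusions transfer to any particular real cohort.

## Numerical choices and degenerate inputs

* Duplicate gene rows collapse to the largest-mean row at read time;
  expression values are assumed log2 (a `log2` flag applies log2(x+1)).
* Constant genes: dropped with a warning before PCA/standardization;
  returned unflagged-but-unadjusted by the batch corrector; screened genes
  yield NA rows rather than failures.
* Consensus entries for never-co-sampled pairs are 0 with a warning;
  with `item_fraction = 1` and the deterministic PAM base clusterer the
  consensus matrix is exactly 0/1.
* Cutpoint ties are broken toward the median score; all-equal scores are
  an error, as is a candidate set with no events on both sides.
* Correlation of a constant vector returns NA with a warning rather than
  an error, since screens feed it programmatically.

## Problem sizes

The default generator (3 × 80 samples, ~3000 genes) matches the scale at
which the planted effects are comfortably identifiable. The test suite and
the acceptance script run consensus clustering at 200 resamples rather
than the 1000-package default — on the planted separations the consensus
matrix is already stable at a few hundred resamples, and the k-selection
and recovery results are identical. Calibration checks use 500–1000
simulations per claim, the smallest sizes at which a 3-standard-error
binomial band around the nominal level is meaningfully tight.

## Known limitations

* The DEG stage does not moderate variances; with very small pattern
  sizes (< ~10 per group) the Wilcoxon option is the safer default.
* The cutpoint search maximizes over many correlated tests, so the
  log-rank p at the chosen cutpoint is optimistic; downstream Cox models
  report the group effect, and any absolute p-value at the cutpoint
  should be treated as descriptive.
* ESTIMATE-style scores are only as good as the supplied signatures;
  no tumor-purity transform is applied.
* CIBERSORT-style deconvolution, external enrichment databases, STRING
  networks and immunophenoscores are out of scope; infiltration claims
  rest on ssGSEA alone.
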