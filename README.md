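# icpattern

Immune checkpoint molecules (PD-1/PD-L1, CTLA4, the CD27/CD70 and
TNFRSF/TNFSF families, ...) regulate anti-tumor immunity as a coordinated
panel, and tumors differ in how the whole panel is expressed. `icpattern`
is an R package plus analysis workflow for discovering those *checkpoint
regulation patterns* in bulk expression cohorts (gastric-cancer-like
settings are the motivating case), scoring individual samples, and relating
the score to immune infiltration, survival, mutation burden and clinical
subtypes. It is aimed at computational biologists running cohort-level
tumor-microenvironment analyses.

## What it computes

Over a fixed 31-gene costimulatory/coinhibitory panel (12 costimulatory,
19 coinhibitory; 17 ligands, 14 receptors):

1. **Batch correction** — empirical-Bayes location/scale adjustment of
   log2 expression across cohorts or batches.
2. **Pattern discovery** — resampling consensus clustering of samples over
   the panel (PAM base clusterer, 80% item subsampling), with the number
   of patterns chosen by the proportion of ambiguous clustering
   (PAC = F(0.9) − F(0.1) of the consensus-entry CDF). Labels are
   canonicalized so pattern **A** is the immune-hot, high-expression
   pattern.
3. **Immune infiltration** — single-sample rank-walk enrichment (ssGSEA,
   weight `rank^0.25`) of immune-cell gene sets, and ESTIMATE-style
   stromal/immune/combined scores.
4. **ICscore** — pattern-contrast DEGs (Welch t + BH per contrast) are
   intersected across all pairwise contrasts; the per-sample score is

   `ICscore_s = sum_i (PC1_{i,s} + PC2_{i,s}) = PC1_s + PC2_s`,

   the sum of the sample's coordinates on the first two principal
   components of the z-scored signature-gene matrix, with components
   oriented so that **low ICscore = immune-hot**. The cohort is split at
   the maximally selected log-rank cutpoint.
5. **Survival statistics** — Kaplan–Meier, log-rank, multivariable Cox
   (Efron ties), and a per-gene univariate prognostic screen.
6. **Genomics** — tumor mutation burden, per-gene mutation frequency by
   score group, pairwise mutation co-occurrence (Fisher exact + BH), and
   CNV gain/loss frequencies.

A synthetic-cohort generator (`simulate_cohort()`) plants all of this
structure — three expression patterns, a latent immune axis driving
infiltration, survival and TMB, batch effects, MAF-like mutations and
clinical subtypes — so the complete pipeline runs and is tested without
any external data. See the methods vignette
(`vignettes/immune-checkpoint-patterns.Rmd`) for the models, defaults and
design rationale.

## Worked example

```r
library(icpattern)

cfg <- pipeline_config(simulate = sim_config(), seed = 1,
                       n_resamples = 200, k_grid = 2:6)
bundle <- run_pipeline(cfg)

cat("chosen k:", bundle$recovery$chosen_k, "\n")
cat("pattern recovery ARI:", round(bundle$recovery$pattern_ari, 3), "\n")
print(round(bundle$recovery$mean_icscore_by_true_pattern, 2))
cat("5-year survival low/high:",
    round(100 * bundle$survival$five_year_survival, 1), "\n")
hr <- bundle$survival$cox$coef[1, ]
cat(sprintf("HR high vs low: %.2f (%.2f-%.2f)\n",
            hr$hr, hr$hr_lower, hr$hr_upper))
cat("Spearman(TMB, ICscore):",
    round(bundle$genomics$tmb_icscore_spearman$statistic, 2), "\n")
```

prints

```
chosen k: 3
pattern recovery ARI: 0.975
     A      B      C
-24.28  -0.23  24.51
5-year survival low/high: 68.5 34.5
HR high vs low: 2.77 (2.03-3.77)
Spearman(TMB, ICscore): -0.75
```

Reading: PAC selects three patterns and they match the planted labels
almost perfectly (ARI 0.975). The immune-hot pattern A has the lowest mean
ICscore, as the sign convention guarantees. Splitting at the
survival-optimal cutpoint, the low-score (immune-hot) group has much
better 5-year survival, the high-score group carries a hazard ratio of
2.8 after adjustment, and the score is strongly anti-correlated with
mutation burden.

The same analysis, stage by stage with tables written under `results/`,
is in `analysis/01_simulate.R` … `analysis/07_genomics.R`; each script is
a thin driver over the package functions and prints what it found.

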