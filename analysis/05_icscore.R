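#!/usr/bin/env Rscript
# Stage 5: derive the checkpoint signature and score every sample.
# Pattern-contrast DEGs (Welch t, BH per contrast) are intersected across
# all pairwise contrasts; samples are re-clustered over those genes
# (geneCluster, k = 2); the ICscore is the PC1+PC2 sample coordinate sum
# of the z-scored signature matrix, oriented so that immune-hot samples
# score LOW; the cohort is split at the survival-optimal cutpoint.

library(icpattern)

expr <- read_expression_matrix("results/expression_corrected.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")
patterns <- read.delim("results/patterns.tsv")
pat <- setNames(patterns$icg_cluster, patterns$sample_id)

degs <- cluster_degs(expr, pat, fdr_threshold = 0.05)
sig <- degs$intersection
cat("signature genes (intersection of all pairwise DEG sets):",
    length(sig), "\n")
writeLines(sig, "results/signature_genes.txt")

gene_fit <- consensus_cluster(expr[sig, ], k = 2, n_resamples = 1000,
                              seed = 500)
gcl <- canonicalize_patterns(gene_fit$assignments, expr[sig, ])

ic <- derive_icscore(expr, sig)
idx <- match(names(ic$score), clinical$sample_id)
cut <- dichotomize_by_cutpoint(ic$score, clinical$os_time[idx],
                               clinical$os_event[idx], minprop = 0.1)
cat("optimal cutpoint:", round(cut$cutpoint, 3),
    " (|z| =", round(cut$statistic, 2), ")\n")
cat("group sizes:", paste(names(table(cut$groups)), table(cut$groups),
                          sep = "=", collapse = "  "), "\n")

tab <- data.frame(sample_id = names(ic$score),
                  icg_cluster = unname(pat[names(ic$score)]),
                  gene_cluster = unname(gcl[names(ic$score)]),
                  icscore = signif(unname(ic$score), 8),
                  icscore_group = unname(cut$groups))
write.table(tab, "results/icscore.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("mean ICscore by checkpoint pattern:\n")
print(round(tapply(ic$score, pat[names(ic$score)], mean), 2))
cat("mean ICscore by geneCluster:\n")
print(round(tapply(ic$score, gcl[names(ic$score)], mean), 2))
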