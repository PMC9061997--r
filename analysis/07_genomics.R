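#!/usr/bin/env Rscript
# Stage 7: mutation landscape by ICscore group. TMB and its correlation
# with the score, per-gene mutation frequencies in the low vs high group,
# pairwise co-occurrence among the most mutated genes, and CNV gain/loss
# frequencies over the checkpoint panel.

library(icpattern)

maf <- read_maf("results/cohort/mutations.maf")
cnv <- read_cnv("results/cohort/cnv.tsv")
icsc <- read.delim("results/icscore.tsv")
ids <- icsc$sample_id

tmb <- compute_tmb(maf, ids)
write.table(tmb, "results/tmb.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
rho <- correlate(tmb$tmb, icsc$icscore, "spearman")
cat("Spearman(TMB, ICscore):", round(rho$statistic, 3),
    " p =", signif(rho$p_value, 3), "\n")
by_grp <- tapply(tmb$tmb, icsc$icscore_group, mean)
cat("mean TMB: low =", round(by_grp["low"], 1),
    " high =", round(by_grp["high"], 1), "\n")

genes <- sort(unique(maf$Hugo_Symbol[
  maf$Variant_Classification %in% nonsyn_classes()]))
freq <- Map(function(s) mutation_frequency(maf, genes, s),
            split(ids, icsc$icscore_group))
cmp <- data.frame(gene = genes,
                  freq_low = freq$low$frequency,
                  freq_high = freq$high$frequency)
write.table(cmp[order(-pmax(cmp$freq_low, cmp$freq_high)), ],
            "results/mutfreq_by_group.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (g in c("ARID1A", "PIK3CA", "TP53"))
  cat(sprintf("%-7s mutated: low %2.0f%%  high %2.0f%%\n", g,
              100 * cmp$freq_low[cmp$gene == g],
              100 * cmp$freq_high[cmp$gene == g]))

overall <- mutation_frequency(maf, genes, ids)
top <- head(overall$gene[order(-overall$frequency)], 15)
cooc <- cooccurrence(maf, top, ids, fdr = 0.05)
write.table(cooc, "results/cooccurrence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("significant co-occurring pairs:",
    sum(cooc$label == "co-occurring"), "\n")

cnvf <- cnv_frequency(cnv)
write.table(cnvf, "results/cnv_frequency.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("panel genes with gain freq > loss freq:",
    sum(cnvf$gain_freq > cnvf$loss_freq), "of", nrow(cnvf), "\n")
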