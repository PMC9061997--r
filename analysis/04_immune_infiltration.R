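#!/usr/bin/env Rscript
# Stage 4: single-sample enrichment of the 28 immune-cell sets (ssGSEA,
# min-max normalized across samples) and ESTIMATE-style stromal/immune
# scores; summarized by checkpoint pattern. The hot pattern A should lead
# on most immune-cell scores and on the immune score.

library(icpattern)

expr <- read_expression_matrix("results/expression_corrected.tsv")
sets <- read_gmt("results/cohort/sets.gmt")
patterns <- read.delim("results/patterns.tsv")
pat <- setNames(patterns$icg_cluster, patterns$sample_id)[colnames(expr)]

cell_sets <- sets[setdiff(names(sets),
                          c("IMMUNE_SIGNATURE", "STROMAL_SIGNATURE"))]
scores <- ssgsea(expr, cell_sets, alpha = 0.25, normalize = "minmax")
write.table(data.frame(set = rownames(scores), scores, check.names = FALSE),
            "results/ssgsea_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

est <- estimate_scores(expr, sets$STROMAL_SIGNATURE, sets$IMMUNE_SIGNATURE)
write.table(est, "results/estimate_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

by_pattern <- t(apply(scores, 1, function(r) tapply(r, pat, mean)))
write.table(data.frame(set = rownames(by_pattern), by_pattern),
            "results/ssgsea_by_pattern.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

frac_a_top <- mean(apply(by_pattern, 1, which.max) == 1)
cat("immune-cell sets with highest mean score in pattern A:",
    round(100 * frac_a_top, 1), "%\n")
imm <- tapply(est$ImmuneScore, pat[est$sample_id], mean)
str <- tapply(est$StromalScore, pat[est$sample_id], mean)
cat("mean ImmuneScore by pattern:", paste(names(imm), round(imm, 2),
                                          sep = "=", collapse = "  "), "\n")
cat("mean StromalScore by pattern:", paste(names(str), round(str, 2),
                                           sep = "=", collapse = "  "), "\n")
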