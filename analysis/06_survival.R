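#!/usr/bin/env Rscript
# Stage 6: prognostic value of the patterns and the ICscore. Kaplan-Meier
# by pattern and by score group, log-rank tests, 5-year survival, a
# multivariable Cox model (score group adjusted for stage and N stage),
# and the univariate screen over the 31 panel genes.

library(icpattern)

clinical <- read_clinical("results/cohort/clinical.tsv")
icsc <- read.delim("results/icscore.tsv")
expr <- read_expression_matrix("results/expression_corrected.tsv")
idx <- match(icsc$sample_id, clinical$sample_id)
time <- clinical$os_time[idx]; event <- clinical$os_event[idx]

lr_pat <- logrank_test(time, event, icsc$icg_cluster)
cat("log-rank across checkpoint patterns: chisq =",
    round(lr_pat$statistic, 2), " p =", signif(lr_pat$p_value, 3), "\n")

lr_grp <- logrank_test(time, event, icsc$icscore_group)
cat("log-rank low vs high ICscore: chisq =", round(lr_grp$statistic, 2),
    " p =", signif(lr_grp$p_value, 3), "\n")

km_tabs <- lapply(split(seq_along(time), icsc$icscore_group), function(i)
  km_estimate(time[i], event[i]))
s5 <- vapply(km_tabs, km_survival_at, 0, t = 60)
cat("5-year survival: low =", round(100 * s5["low"], 1),
    "%  high =", round(100 * s5["high"], 1), "%\n")
km_out <- do.call(rbind, Map(function(tab, g)
  data.frame(group = g, tab), km_tabs, names(km_tabs)))
write.table(km_out, "results/km_by_group.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cox_data <- data.frame(os_time = time, os_event = event,
                       icscore_group = factor(icsc$icscore_group,
                                              c("low", "high")),
                       stage = clinical$stage[idx],
                       n_stage = clinical$n_stage[idx])
cox <- cox_fit(cox_data, c("icscore_group", "stage", "n_stage"))
write.table(cox$coef, "results/cox.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hr <- cox$coef[cox$coef$term == "icscore_grouphigh", ]
cat(sprintf("adjusted HR high vs low ICscore: %.2f (%.2f-%.2f)\n",
            hr$hr, hr$hr_lower, hr$hr_upper))

panel <- expr[intersect(icg_genes(), rownames(expr)), icsc$sample_id]
screen <- univariate_screen(panel, clinical)
write.table(screen, "results/univariate_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("panel genes labeled favorable:",
    sum(screen$direction == "favorable", na.rm = TRUE), "of",
    nrow(screen), "\n")

msi <- contingency_test(icsc$icscore_group, clinical$msi_subtype[idx])
cat("ICscore group vs MSI subtype: chisq p =",
    signif(msi$p_value, 3), "\n")
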