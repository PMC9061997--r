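#!/usr/bin/env Rscript
# Stage 1: generate the synthetic meta-cohort the analysis runs on.
#
# The generator plants three expression patterns (A hot / B intermediate /
# C cold) over the 31-gene immune checkpoint panel, a block of
# pattern-associated background genes, 28 immune-cell gene sets tracking a
# latent immune axis, survival with a protective immune axis, MAF-like
# mutations whose burden rises with the axis, and pattern-dependent
# clinical subtypes, spread over 3 batches.

library(icpattern)

out <- "results/cohort"
cfg <- sim_config(seed = 20260925L)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, out)

cat("cohort written to", out, "\n")
cat("  samples:", ncol(cohort$expression),
    "genes:", nrow(cohort$expression), "\n")
cat("  planted patterns:", paste(names(table(cohort$truth$pattern)),
                                 table(cohort$truth$pattern),
                                 collapse = " "), "\n")
cat("  mutation records:", nrow(cohort$maf), "\n")
cat("  censoring fraction:",
    round(mean(1 - cohort$clinical$os_event), 3), "\n")
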