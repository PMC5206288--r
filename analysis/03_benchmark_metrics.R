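#!/usr/bin/env Rscript
# Bootstrap benchmark statistics (10 000 replicates) over the packaged
# solvation free-energy reference table: MUE and R^2 with 95 % percentile
# intervals for models A-D, water and cyclohexane, whole dataset and
# neutral-only subset. Writes results/benchmark_metrics.csv.

suppressPackageStartupMessages(library(alchlogd))
dir.create("results", showWarnings = FALSE)

res <- reproduce_table1(seed = 1, n_samples = 10000, quiet = FALSE)
write.csv(res, "results/benchmark_metrics.csv", row.names = FALSE)

cat("\nKey readings: adding the long-range dispersion term (model B)\n")
cat("slightly improves the neutral-molecule hydration MUE; the finite-size\n")
cat("charging corrections (model C) repair the two ionic hydration free\n")
cat("energies but degrade cyclohexane solvation; restricting them to\n")
cat("charged species (model D) gives the best overall water MUE.\n")
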