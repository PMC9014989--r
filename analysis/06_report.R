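#!/usr/bin/env Rscript
# Stage 6 — report bundle.
#
# Writes the tidy per-condition tables (performance and heart measures as
# mean +- SD with empty cells for inactive subtasks), the ANOVA/post-hoc and
# correlation tables, and bar figures of the workload score and activation.

suppressMessages(library(flightload))

seed <- 1L
res <- run_study(study_config(seed = seed))
paths <- make_report(res, "results/report",
                     figures = requireNamespace("ggplot2", quietly = TRUE))
cat("Report files written:\n")
cat(paste(" -", paths), sep = "\n")
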