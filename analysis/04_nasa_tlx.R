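#!/usr/bin/env Rscript
# Stage 4 — NASA-TLX synthesis and weighted scoring.
#
# Synthesizes per-subject pairwise-comparison weights and per-condition
# ratings (mental and temporal demand carry the largest load slopes), then
# computes the weighted workload score. The total should climb steadily
# with load.

suppressMessages(library(flightload))

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- study_config(seed = seed)
subjects <- draw_subjects(cfg)
tlx <- study_tlx(cfg, subjects)
write.csv(tlx, "results/tlx_scores.csv", row.names = FALSE)

agg <- aggregate(cbind(md, td, pd, op, ef, fr, tlx_total) ~ condition,
                 data = tlx, FUN = mean)
agg <- agg[match(cfg$conditions, agg$condition), ]
cat("Per-condition NASA-TLX means (dimensions and weighted total):\n")
print(agg, row.names = FALSE, digits = 3)

w <- attr(tlx, "weights")[["s01"]]
cat("\nSubject s01 pairwise weights (sum", sum(w), "):\n")
print(unclass(w))
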