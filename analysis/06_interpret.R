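#!/usr/bin/env Rscript
# Permutation feature importance (AUROC drop) for the static features,
# and the strongest self-attention connections of the final encoder
# layer for one test patient.

library(painattn)

out_dir <- "results/pipeline"
run_pipeline("interpret", config = list(seed = 1L), out_dir = out_dir)

imp <- read.csv(file.path(out_dir, "importance.csv"))
cat("Top 10 static features by permutation importance (AUROC drop):\n")
print(head(imp, 10), row.names = FALSE)

conn <- read.csv(file.path(out_dir, "connections.csv"))
cat("\nTop attention connections (one test patient):\n")
print(conn, row.names = FALSE)
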