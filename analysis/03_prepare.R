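#!/usr/bin/env Rscript
# Split the cohort 70/5/25 (stratified), fit the code vocabulary, static
# schemas and variance thresholds on the training split, and encode
# every split into model inputs.

library(painattn)

out_dir <- "results/pipeline"
run_pipeline("prepare", config = list(seed = 1L), out_dir = out_dir)

prep <- readRDS(file.path(out_dir, "features.rds"))
cat(sprintf("Vocabulary: %d tokens (incl. PAD/UNK)\n",
            prep$features$vocab$size))
cat(sprintf("Demographic inputs: %d (age + variance-selected one-hots)\n",
            prep$features$demo_dim))
cat(sprintf("Survey inputs: %d of %d one-hot pairs retained at p = 0.8\n",
            prep$features$survey_dim,
            length(prep$features$schema$survey_pairs)))
cat(sprintf("Split sizes: train %d / validation %d / test %d\n",
            length(prep$splits$train), length(prep$splits$validation),
            length(prep$splits$test)))
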