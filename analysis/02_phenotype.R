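#!/usr/bin/env Rscript
# Apply the computable chronic-pain phenotype (diagnosis-code rules,
# opioid exposure-duration rule, pain-score exacerbation rule) to the
# simulated cohort and compare against the generator's intended labels.

library(painattn)

out_dir <- "results/pipeline"
run_pipeline("phenotype", config = list(seed = 1L), out_dir = out_dir)

labels <- read.csv(file.path(out_dir, "labels.csv"))
truth <- read.csv(file.path(out_dir, "synthetic_truth.csv"))
m <- match(labels$patient_id, truth$person_id)
agreement <- mean(labels$positive == (truth$outcome[m] == 1))

cat(sprintf("Phenotype positive: %d of %d (%.1f%%)\n", sum(labels$positive),
            nrow(labels), 100 * mean(labels$positive)))
cat("Branch counts:\n")
print(table(labels$branch))
cat(sprintf("Agreement with generator truth: %.1f%%\n", 100 * agreement))
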