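#!/usr/bin/env Rscript
# Phase-I trial simulation: generates the model-building dataset (24
# subjects; 10/20/30 g single doses with a 24 h endogenous baseline day)
# and the validation dataset (7 subjects; 15 g single then BID x 7 days)
# under the final model, and writes both as NONMEM-style CSVs.

suppressPackageStartupMessages(library(serinepk))
dir.create("results", showWarnings = FALSE)
seed <- 123

mb <- simulate_dataset("model_building", seed = seed)
write_pk_dataset(mb, "results/model_building.csv")
val <- simulate_dataset("validation", seed = seed + 1)
write_pk_dataset(val, "results/validation.csv")

obs <- mb[mb$EVID == 0, ]
cat("model-building dataset:", length(unique(mb$ID)), "subjects,",
    nrow(obs), "observations (", sum(obs$DAY == -1), "baseline /",
    sum(obs$DAY == 1), "post-dose )\n")
cat("  doses:", paste(sort(unique(mb$AMT[mb$EVID == 1])), collapse = "/"),
    "g;  min DV:", round(min(obs$DV), 2), "ug/mL (assay LLOQ 4)\n")
cat("validation dataset:", length(unique(val$ID)), "subjects,",
    sum(val$EVID == 0), "observations,", sum(val$EVID == 1),
    "dose records\n")
cat("written: results/model_building.csv, results/validation.csv\n")
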