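#!/usr/bin/env Rscript
# Extract the full 1410-feature PET catalogue for every case written by
# 01_simulate_cohort.R, reading the images back from NIfTI exactly as a
# real-cohort run would. Writes results/features.csv and
# results/catalogue.json.

suppressPackageStartupMessages(library(pleuradiomics))

config <- read_config("results/config.yaml")
outcomes <- utils::read.csv("results/cohort/outcomes.csv")

rows <- lapply(outcomes$case_id, function(id) {
  vol <- read_volume(file.path("results/cohort", paste0(id, "_img.nii.gz")),
                     "PET")
  msk <- read_mask(file.path("results/cohort", paste0(id, "_mask.nii.gz")))
  fv <- extract_all(vol, msk, config)
  c(fv$values, fv$aux)
})
features <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
rownames(features) <- outcomes$case_id
write_features_csv(features, "results/features.csv")
write_catalogue_json(build_catalogue("PET"), "results/catalogue.json")

n_missing <- sum(is.na(features))
cat(sprintf("extracted %d features x %d cases (%d missing cells)\n",
            nrow(build_catalogue("PET")), nrow(features), n_missing))
cat(sprintf("  SUVmax %.1f-%.1f, volume %.1f-%.1f ml\n",
            min(features$SUVmax), max(features$SUVmax),
            min(features$volume_ml), max(features$volume_ml)))
cat("wrote results/features.csv and results/catalogue.json\n")
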