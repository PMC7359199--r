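#!/usr/bin/env Rscript
# Prognostic modeling on the extracted cohort: date-order split into 36
# training + 36 validation patients; prefilter -> Horn-calibrated PCA
# grouping -> univariable Cox screen (BH FDR < 0.25) -> per-group best
# c-index -> multivariate Cox with backward AIC; 5-fold cross-validated
# training c-index; validation with the frozen 80th-percentile risk
# threshold, G-rho (log-rank) stratification and KM medians; SUVmax /
# SUVmean / volume baselines. Writes results/model.json and
# results/report.json.

suppressPackageStartupMessages({
  library(pleuradiomics)
  library(jsonlite)
})

config <- read_config("results/config.yaml")
outcomes <- utils::read.csv("results/cohort/outcomes.csv")
features <- utils::read.csv("results/features.csv", check.names = FALSE)
rownames(features) <- features$case_id
features$case_id <- NULL

cohort <- simulate_cohort(n = nrow(features), beta_true = 1,
                          censor_rate = 0.3, seed = config$master_seed,
                          render = FALSE)
cohort$outcomes <- outcomes   # same seed; reuse the written outcome table

report <- run_pipeline(cohort, config = config, seed = config$master_seed,
                       features = features)

if (is.null(report$model)) {
  cat("no model trained (no component retained or no feature passed FDR)\n")
  write_json(list(model = NULL), "results/model.json", auto_unbox = TRUE)
  quit(status = 0)
}

m <- report$model
cat(sprintf("final model: %d feature(s) from %d PCA groups\n",
            length(m$features), m$k_groups))
for (f in m$features)
  cat(sprintf("  %+0.3f  %s\n", m$coef[[f]], f))
cat(sprintf("training 5-fold CV c-index: %.3f (95%% CI %.3f-%.3f)\n",
            report$cv$mean_c, report$cv$ci[1], report$cv$ci[2]))
cat(sprintf("validation c-index:         %.3f (95%% CI %.3f-%.3f)\n",
            report$validation$c, report$validation$ci[1],
            report$validation$ci[2]))
cat(sprintf("risk threshold (p%d of training linear predictor): %.3f\n",
            m$risk_percentile, m$threshold))
cat(sprintf("validation risk groups: %d low / %d high; G-rho p = %.4f\n",
            report$validation$groups["low"], report$validation$groups["high"],
            report$validation$grho$p))
if (!is.null(report$validation$medians))
  cat(sprintf("median survival: %.1f (low) vs %.1f (high) months\n",
              report$validation$medians["low"],
              report$validation$medians["high"]))
for (b in names(report$baselines))
  cat(sprintf("baseline %-10s train c = %.3f, validation c = %.3f\n", b,
              report$baselines[[b]]$train$c, report$baselines[[b]]$valid$c))

write_json(list(features = m$features, coef = as.list(m$coef),
                center = as.list(m$center), scale = as.list(m$scale),
                threshold = m$threshold,
                risk_percentile = m$risk_percentile,
                k_groups = m$k_groups, seed = config$master_seed,
                config_hash = m$config_hash),
           "results/model.json", auto_unbox = TRUE, digits = NA)
write_json(list(
  cv = list(mean_c = report$cv$mean_c, ci = report$cv$ci),
  validation = list(c = report$validation$c, ci = report$validation$ci,
                    groups = as.list(report$validation$groups),
                    grho_p = report$validation$grho$p,
                    medians = as.list(report$validation$medians)),
  baselines = lapply(report$baselines, function(b)
    list(train_c = b$train$c, valid_c = b$valid$c)),
  manifest = report$manifest),
  "results/report.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/model.json and results/report.json\n")
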