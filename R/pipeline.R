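#' Default pipeline configuration
#'
#' One source of truth for the pipeline constants: 3.3 mm CT and 5.5 mm PET
#' isotropic voxels; the closed -300..200 HU tumor-tissue window; fixed bin
#' widths of 5 HU (CT) and 0.25 SUV (PET); MTV thresholds 20-70% of SUVmax;
#' ICC stability cut-off 0.8; 20% missing-value ceiling; FDR ceiling 0.25 in
#' the univariable screen; the 80th-percentile risk split; 5-fold cross
#' validation; log-rank (`rho = 0`) G-rho test; significance level 0.05.
#'
#' @param master_seed Integer master seed recorded in the config.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(master_seed = 1L) {
  structure(list(
    ct_voxel_mm = 3.3,
    pet_voxel_mm = 5.5,
    hu_window = c(-300, 200),
    ct_bin = 5,
    pet_bin = 0.25,
    mtv_thresholds = seq(0.2, 0.7, by = 0.1),
    icc_threshold = 0.8,
    max_missing = 0.20,
    var_tol = 1e-8,
    fdr_max = 0.25,
    risk_percentile = 80,
    cv_folds = 5,
    grho_rho = 0,
    horn_criterion = "mean",
    horn_n_sim = 50,
    n_boot = 1000,
    alpha = 0.05,
    master_seed = as.integer(master_seed)),
    class = c("pipeline_config", "list"))
}

#' Serialize / restore a configuration
#'
#' Round-trips the full config through YAML so a run can be reproduced from
#' its manifest alone.
#'
#' @param config A [default_config()] list.
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$master_seed <- as.integer(cfg$master_seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

# Small stable FNV-1a hash of the deparsed config for the run manifest.
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 21661362
  for (b in bytes)
    h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Train the radiomics risk model
#'
#' The full statistical chain on a training cohort: prefilter (missingness
#' and variability), Horn-calibrated PCA feature grouping, univariable Cox
#' screening with BH FDR control, per-group best-c-index selection,
#' multivariate Cox with backward AIC selection, and the percentile risk
#' threshold frozen on the training linear predictors. Returns `NULL`
#' (with a message) when no feature qualifies — the "no model trained"
#' outcome.
#'
#' @param features data.frame, rows = patients (catalogue columns; may
#'   contain `NA`).
#' @param time,event Outcome vectors.
#' @param config A [default_config()] list.
#' @param seed Integer seed (Horn simulations).
#' @return A `risk_model` list (`features`, `coef`, `center`, `scale`,
#'   `threshold`, `k_groups`, `prefilter_medians`, `screen`, `groups`) or
#'   `NULL` if no model can be trained.
#' @export
train_risk_model <- function(features, time, event,
                             config = default_config(), seed = 1L) {
  pf <- prefilter(features, config$max_missing, config$var_tol)
  X <- as.matrix(pf$features)
  k <- horn_parallel(X, n_sim = config$horn_n_sim, seed = seed,
                     criterion = config$horn_criterion)
  if (k < 1L) {
    message("no model trained: parallel analysis retained no component")
    return(NULL)
  }
  grp <- pca_group(X, k)
  screen <- univariable_screen(pf$features, time, event)
  sel <- select_per_group(screen, grp$groups, config$fdr_max)
  if (length(sel) == 0L) {
    message("no model trained: no feature passed the FDR ceiling")
    return(NULL)
  }
  fit <- backward_aic(pf$features, time, event, candidates = sel)
  if (!fit$ok) {
    message("no model trained: multivariate Cox fit failed")
    return(NULL)
  }
  split <- risk_split(fit$linpred, percentile = config$risk_percentile)
  structure(list(features = fit$selected, coef = fit$coef,
                 center = fit$center, scale = fit$scale,
                 threshold = split$threshold,
                 risk_percentile = config$risk_percentile,
                 k_groups = grp$k, groups = grp$groups, screen = screen,
                 prefilter_medians = pf$medians, seed = seed,
                 config_hash = config_hash(config)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d feature(s), threshold %.3f (p%d)\n",
              length(x$features), x$threshold, x$risk_percentile))
  for (f in x$features)
    cat(sprintf("  %+.3f  %s\n", x$coef[[f]], f))
  invisible(x)
}

#' Linear predictor of a risk model on new patients
#'
#' Applies the frozen training standardization and coefficients.
#'
#' @param model A `risk_model`.
#' @param features data.frame with the model's feature columns (missing
#'   entries imputed with the frozen training medians).
#' @return Numeric vector of linear predictors.
#' @export
predict_risk <- function(model, features) {
  X <- as.data.frame(features, check.names = FALSE)[, model$features,
                                                    drop = FALSE]
  for (nm in names(X)) {
    i <- is.na(X[[nm]])
    if (any(i)) X[[nm]][i] <- model$prefilter_medians[[nm]]
  }
  Z <- sweep(sweep(as.matrix(X), 2, model$center[model$features]), 2,
             model$scale[model$features], "/")
  as.vector(Z %*% model$coef[model$features])
}

#' Validate a risk model on a cohort
#'
#' Scores the cohort with the frozen model, reporting the Harrell c-index
#' with a bootstrap CI, the risk-group split at the frozen training
#' threshold, the G-rho stratification test and per-group KM medians.
#'
#' @param model A [train_risk_model()] result.
#' @param features,time,event Cohort data.
#' @param config A [default_config()] list.
#' @param seed Integer seed (bootstrap).
#' @return List: `c` (+`ci`), `groups` (sizes), `grho` (`chisq`, `p`),
#'   `medians` (per group), `threshold`.
#' @export
validate_model <- function(model, features, time, event,
                           config = default_config(), seed = 1L) {
  lp <- predict_risk(model, features)
  cc <- c_with_ci(lp, time, event, config$n_boot, seed)
  split <- risk_split(lp, threshold = model$threshold)
  out <- list(c = cc$c, ci = cc$ci, threshold = model$threshold,
              groups = table(split$group), degenerate = split$degenerate)
  if (!split$degenerate && all(table(split$group) > 0)) {
    out$grho <- grho_test(time, event, split$group, rho = config$grho_rho)
    out$medians <- c(
      low = km_median(time[split$group == "low"],
                      event[split$group == "low"]),
      high = km_median(time[split$group == "high"],
                       event[split$group == "high"]))
  }
  out
}

#' End-to-end pipeline on a simulated cohort
#'
#' Extracts the full feature catalogue for every case, splits the cohort
#' into training and validation halves (first/second half, mirroring a
#' split by treatment date), trains the risk model on the training half,
#' estimates its cross-validated c-index, and validates on the held-out
#' half. Also fits the scalar baselines (SUVmax, SUVmean, volume for PET;
#' volume for CT).
#'
#' @param cohort A [simulate_cohort()] result with rendered phantoms, or a
#'   precomputed feature data.frame via `features`.
#' @param config A [default_config()] list.
#' @param seed Integer seed for all stochastic stages.
#' @param features Optional precomputed [extract_cohort()] table.
#' @return List of class `pipeline_report`: `model` (or `NULL`),
#'   `cv` (training cross-validation), `validation`, `baselines`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, config = default_config(), seed = 1L,
                         features = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (is.null(features)) features <- extract_cohort(cohort, config)
  n <- nrow(features)
  if (n < 4L) stop("cohort too small to split")
  modality <- cohort$cases[[1]]$volume$modality %||% "PET"
  cat_names <- build_catalogue(modality)$name
  aux <- features[, setdiff(colnames(features), cat_names), drop = FALSE]
  feat <- features[, intersect(colnames(features), cat_names), drop = FALSE]
  tr <- seq_len(floor(n / 2))
  va <- setdiff(seq_len(n), tr)
  time <- cohort$outcomes$time_months
  event <- cohort$outcomes$event
  seeds <- split_seed(seed, 4L)
  model <- train_risk_model(feat[tr, , drop = FALSE], time[tr], event[tr],
                            config, seed = seeds[1L])
  report <- list(model = model, n_train = length(tr), n_valid = length(va))
  if (!is.null(model)) {
    report$cv <- cv_cindex(prefilter(feat[tr, , drop = FALSE],
                                     config$max_missing, config$var_tol,
                                     medians = model$prefilter_medians)$features,
                           time[tr], event[tr], model$features,
                           folds = config$cv_folds, seed = seeds[2L],
                           n_boot = config$n_boot)
    report$validation <- validate_model(model, feat[va, , drop = FALSE],
                                        time[va], event[va], config,
                                        seed = seeds[3L])
  }
  scalars <- intersect(c("SUVmax", "SUVmean", "volume_ml"), colnames(aux))
  report$baselines <- lapply(stats::setNames(scalars, scalars), function(s)
    baseline_scalar_model(aux[tr, s], time[tr], event[tr],
                          aux[va, s], time[va], event[va],
                          n_boot = config$n_boot, seed = seeds[4L]))
  report$manifest <- list(config_hash = config_hash(config), seed = seed,
                          n = n, modality = modality,
                          package_version = as.character(
                            utils::packageVersion("pleuradiomics")),
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  class(report) <- "pipeline_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  if (is.null(x$model)) {
    cat("<pipeline_report> no model trained\n")
  } else {
    cat(sprintf(
      "<pipeline_report> %d features; CV c = %.3f; validation c = %.3f\n",
      length(x$model$features), x$cv$mean_c, x$validation$c))
  }
  invisible(x)
}
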