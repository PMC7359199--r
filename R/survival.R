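#' Prefilter a feature table for modeling
#'
#' Drops features with more than `max_missing` missing values (strict: a
#' fraction of exactly `max_missing` is retained) or with near-zero
#' variance; remaining missing entries are imputed with the feature median
#' computed on the supplied (training) rows, or with externally supplied
#' medians for a validation cohort.
#'
#' @param features data.frame or matrix, rows = patients.
#' @param max_missing Maximum tolerated missing fraction (default 0.20).
#' @param var_tol Variance threshold on the complete-case values; features
#'   with variance `<= var_tol` are dropped (default 1e-8).
#' @param medians Optional named vector of imputation medians (from a
#'   training-cohort prefilter) to apply instead of recomputing.
#' @return List: `features` (filtered, imputed data.frame), `kept`
#'   (character), `medians` (named vector used for imputation).
#' @export
prefilter <- function(features, max_missing = 0.20, var_tol = 1e-8,
                      medians = NULL) {
  X <- as.data.frame(features, check.names = FALSE)
  miss <- vapply(X, function(x) mean(is.na(x)), 0)
  keep <- miss <= max_missing
  vars <- vapply(X, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else stats::var(x)
  }, 0)
  keep <- keep & vars > var_tol
  if (!any(keep)) stop("prefilter removed every feature")
  X <- X[, keep, drop = FALSE]
  if (is.null(medians))
    medians <- vapply(X, function(x) stats::median(x, na.rm = TRUE), 0)
  for (nm in names(X)) {
    i <- is.na(X[[nm]])
    if (any(i)) X[[nm]][i] <- medians[[nm]]
  }
  list(features = X, kept = names(X), medians = medians[names(X)])
}

#' Horn's parallel analysis for the number of retained components
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' eigenvalue spectrum of `n_sim` simulated iid standard-normal data sets of
#' the same size. The retained count `k` is the length of the leading run of
#' observed eigenvalues exceeding the criterion (the simulated mean by
#' default, or the simulated 95th percentile).
#'
#' @param X Numeric matrix, n x p (n >= 3, p >= 2); columns are
#'   standardized internally.
#' @param n_sim Number of simulated spectra (default 50).
#' @param seed Integer seed.
#' @param criterion `"mean"` (default) or `"p95"`.
#' @return Integer k (possibly 0).
#' @export
horn_parallel <- function(X, n_sim = 50, seed = 1L,
                          criterion = c("mean", "p95")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L || p < 2L) stop("need n >= 3 and p >= 2")
  obs <- cor_eigenvalues(X)
  sims <- with_seed(seed, vapply(seq_len(n_sim), function(s)
    cor_eigenvalues(matrix(stats::rnorm(n * p), n, p)), numeric(length(obs))))
  crit <- if (criterion == "mean") rowMeans(sims)
          else apply(sims, 1, pctl, 0.95)
  above <- obs > crit
  k <- 0L
  while (k < length(above) && above[k + 1L]) k <- k + 1L
  k
}

# Eigenvalues of the correlation matrix via SVD of the standardized data;
# handles p > n without forming a p x p matrix. Constant columns get zero
# weight (their correlations are undefined).
cor_eigenvalues <- function(X) {
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- Inf
  Z <- scale(X, center = TRUE, scale = sds)
  d <- svd(Z, nu = 0, nv = 0)$d
  ev <- numeric(min(dim(X)))
  ev[seq_along(d)] <- d^2 / (n - 1)
  ev
}

#' Group features by their dominant principal component
#'
#' PCA on the correlation scale; the retained loadings are varimax-rotated
#' (which leaves the retained subspace untouched but makes the assignment
#' well defined when leading eigenvalues are close), then each feature is
#' assigned to the component on which it has the largest absolute loading.
#'
#' @param X Numeric matrix n x p.
#' @param k Number of retained components (1 <= k <= rank).
#' @return List: `k`, `groups` (named integer vector, feature -> group in
#'   1..k).
#' @export
pca_group <- function(X, k) {
  X <- as.matrix(X)
  if (k < 1L) stop("'k' must be >= 1")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant feature column; prefilter first")
  Z <- scale(X)
  sv <- svd(Z, nu = 0, nv = k)
  if (k > sum(sv$d > 1e-8 * sv$d[1]))
    stop(sprintf("k = %d exceeds the rank of the standardized matrix", k))
  load <- sv$v %*% diag(sv$d[seq_len(k)] / sqrt(nrow(X) - 1), k)
  if (k >= 2L)
    load <- stats::varimax(load, normalize = FALSE)$loadings
  grp <- apply(abs(load), 1, which.max)
  names(grp) <- colnames(X)
  list(k = as.integer(k), groups = grp)
}

#' Cox proportional-hazards fit on standardized covariates
#'
#' Maximum partial likelihood with Efron tie handling via
#' [survival::coxph()]. Covariates are standardized with the supplied (or
#' internally computed) means and SDs, so coefficients are log hazard
#' ratios per SD. Non-convergence or numerical separation is flagged rather
#' than raised, letting screening treat the feature as non-informative.
#'
#' @param X Matrix or data.frame of covariates (>= 1 column).
#' @param time,event Outcome vectors; at least one event required.
#' @param center,scale Optional standardization parameters (training
#'   statistics when scoring a validation cohort).
#' @return List: `coef` (named), `center`, `scale`, `loglik`, `aic`,
#'   `linpred`, `p` (per-coefficient Wald p), `ok` (logical convergence
#'   flag), `fit` (the `coxph` object or `NULL`).
#' @export
cox_fit <- function(X, time, event, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (sum(event) < 1) stop("no events: cannot fit a Cox model")
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    if (any(scale == 0)) stop("zero-variance covariate")
  }
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  colnames(Z) <- colnames(X)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ Z, ties = "efron"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || any(!is.finite(stats::coef(fit))) ||
      any(abs(stats::coef(fit)) > 20)) {
    return(list(coef = stats::setNames(rep(0, ncol(Z)), colnames(Z)),
                center = center, scale = scale, loglik = NA_real_,
                aic = NA_real_, linpred = rep(0, nrow(Z)),
                p = rep(1, ncol(Z)), ok = FALSE, fit = NULL))
  }
  cf <- stats::setNames(stats::coef(fit), colnames(Z))
  se <- sqrt(diag(fit$var))
  list(coef = cf, center = center, scale = scale,
       loglik = fit$loglik[2],
       aic = -2 * fit$loglik[2] + 2 * length(cf),
       linpred = as.vector(Z %*% cf),
       p = 2 * stats::pnorm(-abs(cf / se)), ok = TRUE, fit = fit)
}

#' Harrell's concordance index
#'
#' Fraction of permissible patient pairs whose risk ordering matches their
#' survival ordering, with half credit for risk ties; oriented so that a
#' hazard-increasing predictor (higher `linpred`, shorter survival) scores
#' above 0.5. A pair is permissible if the shorter time is an event (ties
#' in time with both events are not permissible).
#'
#' @param linpred Risk score (linear predictor) per patient.
#' @param time,event Outcome vectors.
#' @return Concordance in \[0, 1\], or `NA` if no pair is permissible.
#' @export
harrell_c <- function(linpred, time, event) {
  n <- length(linpred)
  conc <- 0; perm <- 0
  o <- order(time)
  linpred <- linpred[o]; time <- time[o]; event <- event[o]
  for (i in seq_len(n - 1L)) {
    if (event[i] != 1) next
    js <- which(time > time[i])
    if (length(js) == 0L) next
    perm <- perm + length(js)
    conc <- conc + sum(linpred[i] > linpred[js]) +
      0.5 * sum(linpred[i] == linpred[js])
  }
  if (perm == 0) return(NA_real_)
  conc / perm
}

#' Univariable Cox screen over all features
#'
#' Per-feature univariable Cox fit with the Harrell c-index of the fitted
#' risk direction and Benjamini-Hochberg q-values computed across all
#' screened features.
#'
#' @param features data.frame/matrix, rows = patients (no missing values —
#'   run [prefilter()] first).
#' @param time,event Outcome vectors.
#' @return data.frame: `feature`, `coef`, `cindex`, `p`, `q`, ordered as
#'   the input columns.
#' @export
univariable_screen <- function(features, time, event) {
  X <- as.matrix(features)
  res <- lapply(seq_len(ncol(X)), function(j) {
    f <- cox_fit(X[, j, drop = FALSE], time, event)
    ci <- if (f$ok) harrell_c(f$linpred, time, event) else 0.5
    data.frame(feature = colnames(X)[j], coef = unname(f$coef[1]),
               cindex = ci, p = unname(f$p[1]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Select the best feature per principal-component group
#'
#' Within each group, picks the feature with the highest c-index among those
#' with BH q-value strictly below `fdr_max`; groups with no qualifying
#' feature contribute nothing. An empty result signals "no model trained".
#'
#' @param screen A [univariable_screen()] result.
#' @param groups Named integer vector (feature -> group), as from
#'   [pca_group()].
#' @param fdr_max FDR ceiling (default 0.25).
#' @return Character vector of selected feature names (possibly empty).
#' @export
select_per_group <- function(screen, groups, fdr_max = 0.25) {
  sel <- character(0)
  for (g in sort(unique(groups))) {
    cand <- screen[screen$feature %in% names(groups)[groups == g] &
                     screen$q < fdr_max & !is.na(screen$cindex), ]
    if (nrow(cand) == 0L) next
    sel <- c(sel, cand$feature[which.max(cand$cindex)])
  }
  sel
}

#' Backward AIC selection in a multivariate Cox model
#'
#' Starting from all candidates, iteratively removes the feature whose
#' removal most lowers `AIC = -2 logPL + 2 * #features` until no removal
#' improves it, then refits the final coefficients.
#'
#' @param features data.frame/matrix of candidate covariates.
#' @param time,event Outcome vectors.
#' @param candidates Character vector of starting features (default: all
#'   columns).
#' @return A `cox_fit` result restricted to the surviving features, with an
#'   extra element `selected`.
#' @export
backward_aic <- function(features, time, event,
                         candidates = colnames(as.data.frame(features))) {
  X <- as.matrix(as.data.frame(features, check.names = FALSE)[, candidates,
                                                              drop = FALSE])
  if (ncol(X) < 1L) stop("need at least one candidate feature")
  current <- colnames(X)
  fit <- cox_fit(X[, current, drop = FALSE], time, event)
  repeat {
    if (length(current) <= 1L) break
    aics <- vapply(current, function(drop1) {
      f <- cox_fit(X[, setdiff(current, drop1), drop = FALSE], time, event)
      if (f$ok) f$aic else Inf
    }, 0)
    cur_aic <- if (fit$ok && is.finite(fit$aic)) fit$aic else Inf
    if (all(is.infinite(aics)) && is.infinite(cur_aic)) break
    if (min(aics) < cur_aic - 1e-12) {
      current <- setdiff(current, names(which.min(aics)))
      fit <- cox_fit(X[, current, drop = FALSE], time, event)
    } else break
  }
  fit$selected <- current
  fit
}

#' Cross-validated concordance of a fixed feature set
#'
#' Event-stratified k-fold assignment; on each fold the Cox coefficients
#' (not the feature set) are refit on the training part and the held-out
#' linear predictors are scored. Reports the mean of per-fold c-indices
#' with a patient-level bootstrap CI of the pooled out-of-fold concordance.
#'
#' @param features,time,event Cohort data (no missing values).
#' @param feature_set Character vector of model features.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (fold assignment and bootstrap).
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @return List: `mean_c`, `ci` (length-2), `per_fold`.
#' @export
cv_cindex <- function(features, time, event, feature_set, folds = 5,
                      seed = 1L, n_boot = 1000) {
  X <- as.matrix(as.data.frame(features, check.names = FALSE)[, feature_set,
                                                              drop = FALSE])
  n <- nrow(X)
  seeds <- split_seed(seed, 2L)
  fold_of <- with_seed(seeds[1L], {
    f <- integer(n)
    for (retry in 1:25) {
      # stratified by event status so every fold sees events
      for (s in unique(event)) {
        idx <- which(event == s)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      ok <- all(vapply(seq_len(folds),
                       function(k) sum(event[f != k]) >= 1, TRUE))
      if (ok) break
    }
    if (!ok) stop("could not build folds with events in every training part")
    f
  })
  oof <- rep(NA_real_, n)
  per_fold <- rep(NA_real_, folds)
  for (k in seq_len(folds)) {
    tr <- fold_of != k
    fit <- cox_fit(X[tr, , drop = FALSE], time[tr], event[tr])
    Z <- sweep(sweep(X[!tr, , drop = FALSE], 2, fit$center), 2, fit$scale, "/")
    oof[!tr] <- as.vector(Z %*% fit$coef)
    per_fold[k] <- harrell_c(oof[!tr], time[!tr], event[!tr])
  }
  boots <- with_seed(seeds[2L], vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    harrell_c(oof[i], time[i], event[i])
  }, 0))
  list(mean_c = mean(per_fold, na.rm = TRUE),
       ci = pctl(boots[!is.na(boots)], c(0.025, 0.975)),
       per_fold = per_fold)
}

#' Split a cohort into risk groups at a training percentile
#'
#' The threshold is the stated percentile (linear-interpolation rule) of
#' the training linear predictors; high risk means linear predictor
#' strictly above the threshold. A frozen training threshold applied to a
#' validation cohort need not reproduce the percentile split.
#'
#' @param linpred Linear predictors of the cohort being split.
#' @param threshold Either a frozen numeric threshold, or `NULL` to compute
#'   it from `linpred` at `percentile`.
#' @param percentile Percentile (0-100) used when `threshold` is `NULL`.
#' @return List: `group` (factor `low`/`high`), `threshold`, `degenerate`
#'   (TRUE when all predictors are equal and no split exists).
#' @export
risk_split <- function(linpred, threshold = NULL, percentile = 80) {
  if (is.null(threshold)) threshold <- pctl(linpred, percentile / 100)
  degenerate <- length(unique(linpred)) == 1L
  group <- factor(ifelse(linpred > threshold, "high", "low"),
                  levels = c("low", "high"))
  list(group = group, threshold = threshold, degenerate = degenerate)
}

#' Harrington-Fleming G-rho test between risk groups
#'
#' Weighted log-rank family via [survival::survdiff()]; `rho = 0` is the
#' log-rank test, `rho = 1` the Peto-Peto modification.
#'
#' @param time,event Outcome vectors.
#' @param group Two-level grouping (both levels non-empty).
#' @param rho Weight exponent (default 0).
#' @return List: `chisq`, `p`.
#' @export
grho_test <- function(time, event, group, rho = 0) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L || any(table(group) == 0L))
    stop("need two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = rho)
  list(chisq = sd$chisq, p = 1 - stats::pchisq(sd$chisq, df = 1))
}

#' Kaplan-Meier median survival
#'
#' First time at which the Kaplan-Meier estimate drops to 0.5 or below;
#' `NA` if the curve never reaches 0.5.
#'
#' @param time,event Outcome vectors.
#' @return Median survival time (months), possibly `NA`.
#' @export
km_median <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  i <- which(fit$surv <= 0.5)
  if (length(i) == 0L) NA_real_ else fit$time[min(i)]
}

#' Baseline scalar prognostic model
#'
#' Univariable Cox model on a routine scalar (SUVmax, SUVmean or volume)
#' with the same c-index machinery as the radiomics model, to quantify the
#' added value of the texture features.
#'
#' @param scalar_train,time_train,event_train Training data.
#' @param scalar_valid,time_valid,event_valid Optional validation data.
#' @param n_boot Bootstrap resamples for CIs.
#' @param seed Integer seed.
#' @return List with `train` and (optionally) `valid`, each `c` + `ci`.
#' @export
baseline_scalar_model <- function(scalar_train, time_train, event_train,
                                  scalar_valid = NULL, time_valid = NULL,
                                  event_valid = NULL, n_boot = 1000,
                                  seed = 1L) {
  fit <- cox_fit(matrix(scalar_train, ncol = 1,
                        dimnames = list(NULL, "scalar")),
                 time_train, event_train)
  out <- list(train = c_with_ci(fit$linpred, time_train, event_train,
                                n_boot, split_seed(seed, 2L)[1L]),
              coef = unname(fit$coef[1]))
  if (!is.null(scalar_valid)) {
    lp <- (scalar_valid - fit$center[1]) / fit$scale[1] * fit$coef[1]
    out$valid <- c_with_ci(lp, time_valid, event_valid, n_boot,
                           split_seed(seed, 2L)[2L])
  }
  out
}

c_with_ci <- function(linpred, time, event, n_boot, seed) {
  n <- length(linpred)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    harrell_c(linpred[i], time[i], event[i])
  }, 0))
  list(c = harrell_c(linpred, time, event),
       ci = pctl(boots[!is.na(boots)], c(0.025, 0.975)))
}
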