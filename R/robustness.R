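#' Intraclass correlation of one feature across observers
#'
#' Two-way ICC from the cases x observers ANOVA decomposition. The default
#' variant is ICC(3,1) — two-way mixed effects, consistency, single measure:
#' `(BMS - EMS) / (BMS + (k-1) EMS)` with `BMS` the between-cases and `EMS`
#' the residual mean square. Consistency ICC ignores fixed observer offsets;
#' the `"agreement"` variant (ICC(2,1)) penalizes them. A matrix with zero
#' total variance is perfectly consistent and returns 1.
#'
#' @param m Numeric matrix, rows = cases (>= 2), columns = observers (>= 2),
#'   no missing cells.
#' @param type `"consistency"` (ICC(3,1), default) or `"agreement"`
#'   (ICC(2,1)).
#' @return ICC value in (-Inf, 1].
#' @export
icc_consistency <- function(m, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (anyNA(m)) stop("ICC input must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 cases and >= 2 observers")
  grand <- mean(m)
  if (all(abs(m - grand) < 1e-300)) return(1)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  bms <- ssr / (n - 1)
  jms <- ssc / (k - 1)
  ems <- sse / ((n - 1) * (k - 1))
  if (bms + (k - 1) * ems == 0) return(1)
  if (type == "consistency") {
    (bms - ems) / (bms + (k - 1) * ems)
  } else {
    den <- bms + (k - 1) * ems + k * (jms - ems) / n
    if (den == 0) 1 else (bms - ems) / den
  }
}

#' Assemble a cases x observers x features table
#'
#' @param values Numeric array `cases x observers x features` (dimnames on
#'   the third margin give feature names), or a long data.frame with columns
#'   `case_id`, `observer_id`, `feature`, `value`.
#' @return An `observer_feature_table` (validated 3D array).
#' @export
observer_feature_table <- function(values) {
  if (is.data.frame(values)) {
    need <- c("case_id", "observer_id", "feature", "value")
    if (!all(need %in% names(values)))
      stop("long input needs columns case_id, observer_id, feature, value")
    cases <- unique(values$case_id)
    obs <- unique(values$observer_id)
    feats <- unique(values$feature)
    arr <- array(NA_real_, c(length(cases), length(obs), length(feats)),
                 dimnames = list(cases, obs, feats))
    arr[cbind(match(values$case_id, cases),
              match(values$observer_id, obs),
              match(values$feature, feats))] <- values$value
    values <- arr
  }
  if (length(dim(values)) != 3L)
    stop("expected a 3D cases x observers x features array")
  if (dim(values)[1] < 2L || dim(values)[2] < 2L)
    stop("need >= 2 cases and >= 2 observers")
  if (is.null(dimnames(values)[[3]]))
    dimnames(values)[[3]] <- sprintf("feature_%d", seq_len(dim(values)[3]))
  structure(values, class = "observer_feature_table")
}

#' Inter-observer stability filter
#'
#' Computes the per-feature ICC across observers and keeps features with
#' ICC strictly above the threshold (the threshold value itself fails).
#' Features with any missing cell are classified unstable without computing
#' an ICC — an undefined feature cannot be called robust.
#'
#' @param table An [observer_feature_table()] (or coercible input).
#' @param threshold Stability cut-off on the ICC (default 0.8).
#' @param type ICC variant, see [icc_consistency()].
#' @return A list: `stable` (character vector of retained feature names) and
#'   `report` (data.frame `feature`, `icc`, `retained`).
#' @export
stability_filter <- function(table, threshold = 0.8,
                             type = c("consistency", "agreement")) {
  type <- match.arg(type)
  if (!inherits(table, "observer_feature_table"))
    table <- observer_feature_table(table)
  feats <- dimnames(table)[[3]]
  icc <- vapply(seq_along(feats), function(f) {
    m <- table[, , f]
    if (anyNA(m)) NA_real_ else icc_consistency(m, type)
  }, 0)
  retained <- !is.na(icc) & icc > threshold
  list(stable = feats[retained],
       report = data.frame(feature = feats, icc = icc, retained = retained,
                           stringsAsFactors = FALSE))
}
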