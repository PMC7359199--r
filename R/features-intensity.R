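# Percentile rule used throughout the package: linear interpolation between
# order statistics (stats::quantile type 7).
pctl <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)

#' First-order intensity statistics
#'
#' The 17 intensity features of the catalogue, computed from the raw (not
#' discretized) in-mask intensities. Moments use the population (1/N)
#' convention; kurtosis is excess kurtosis. Features that are undefined on
#' the input (skewness of a constant region, coefficient of variation at
#' zero mean) are returned as `NA`.
#'
#' @param x Numeric vector of in-mask intensities (length >= 1).
#' @return Named numeric vector of length 17 (names prefixed `intensity`).
#' @export
intensity_features <- function(x) {
  if (length(x) < 1L) stop("no in-mask intensities")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdev <- sqrt(m2)
  q1 <- pctl(x, 0.25); q3 <- pctl(x, 0.75)
  p10 <- pctl(x, 0.10); p90 <- pctl(x, 0.90)
  mid <- x[x >= p10 & x <= p90]
  c("intensity mean" = mu,
    "intensity variance" = m2,
    "intensity skewness" = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_,
    "intensity kurtosis" = if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else NA_real_,
    "intensity median" = stats::median(x),
    "intensity minimum" = min(x),
    "intensity 10th percentile" = p10,
    "intensity 90th percentile" = p90,
    "intensity maximum" = max(x),
    "intensity interquartile range" = q3 - q1,
    "intensity range" = max(x) - min(x),
    "intensity mean absolute deviation" = mean(abs(x - mu)),
    "intensity robust mean absolute deviation" =
      mean(abs(mid - mean(mid))),
    "intensity coefficient of variation" =
      if (mu != 0) sdev / mu else NA_real_,
    "intensity quartile coefficient of dispersion" =
      if ((q3 + q1) != 0) (q3 - q1) / (q3 + q1) else NA_real_,
    "intensity energy" = sum(x^2),
    "intensity root mean square" = sqrt(mean(x^2)))
}

#' Metabolic tumor volume at fractional SUVmax thresholds
#'
#' `MTV_t` is the volume (ml) of in-mask voxels with SUV at or above
#' `t * SUVmax`, for thresholds 20% to 70% of the maximum uptake.
#'
#' @param suv_values In-mask SUVs (length >= 1).
#' @param voxel_volume_ml Volume of one voxel in ml.
#' @param thresholds Fractional thresholds of SUVmax.
#' @return Named numeric vector (`MTV20` ... `MTV70`).
#' @export
mtv_features <- function(suv_values, voxel_volume_ml,
                         thresholds = seq(0.2, 0.7, by = 0.1)) {
  if (length(suv_values) < 1L) stop("no in-mask SUV values")
  mx <- max(suv_values)
  out <- vapply(thresholds,
                function(t) voxel_volume_ml * sum(suv_values >= t * mx), 0)
  names(out) <- sprintf("MTV%d", round(100 * thresholds))
  out
}
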