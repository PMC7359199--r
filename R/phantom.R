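#' Specification of a heterogeneous lesion phantom
#'
#' Describes a spherical lesion embedded in a uniform background, with a
#' controllable within-lesion texture amplitude. The texture is band-limited
#' (Gaussian-smoothed) noise rescaled to unit standard deviation inside the
#' lesion, so `heterogeneity` is the within-lesion texture SD in intensity
#' units and drives both intensity-variance and texture features.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing Numeric length-3, mm per axis.
#' @param lesion_radius Lesion radius in mm; must fit inside the grid
#'   (radius < half of the smallest physical extent).
#' @param background_level,lesion_level Intensities (HU or SUV).
#' @param heterogeneity Texture amplitude h >= 0 (intensity units).
#' @param noise_sigma Global additive white-noise SD >= 0.
#' @param texture_scale_mm Correlation length of the lesion texture field
#'   (Gaussian smoothing sigma, mm).
#' @param modality `"CT"` or `"PET"`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 16L),
                         spacing = c(5.5, 5.5, 5.5),
                         lesion_radius = 18,
                         background_level = 0.5,
                         lesion_level = 5,
                         heterogeneity = 0.5,
                         noise_sigma = 0.15,
                         texture_scale_mm = 8,
                         modality = c("PET", "CT")) {
  modality <- match.arg(modality)
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("'grid_shape' must be 3 integers >= 2")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive mm values")
  if (heterogeneity < 0 || noise_sigma < 0)
    stop("'heterogeneity' and 'noise_sigma' must be >= 0")
  extent <- (grid_shape - 1L) * spacing
  if (lesion_radius >= min(extent) / 2)
    stop(sprintf(
      "lesion radius %.1f mm does not fit: half of smallest extent is %.1f mm",
      lesion_radius, min(extent) / 2))
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 lesion_radius = lesion_radius,
                 background_level = background_level,
                 lesion_level = lesion_level,
                 heterogeneity = heterogeneity, noise_sigma = noise_sigma,
                 texture_scale_mm = texture_scale_mm, modality = modality),
            class = "phantom_spec")
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. This is the single seed-splitting primitive: every
# stochastic operation derives its sub-seeds through it.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Draw `n` independent sub-seeds (< 2^31) from a master seed.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels per axis.
# Kernel rows renormalized at the edges (replicate boundary behaviour).
smooth_gaussian <- function(arr, sigma_vox) {
  out <- arr
  for (a in 1:3) {
    n <- dim(out)[a]
    s <- sigma_vox[a]
    if (s <= 0) next
    S <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - j)^2) / (2 * s^2)))
    S <- S / rowSums(S)
    perm <- c(a, setdiff(1:3, a))
    x <- aperm(out, perm)
    d <- dim(x)
    x <- array(S %*% matrix(x, nrow = d[1L]), d)
    out <- aperm(x, order(perm))
  }
  out
}

#' Render a spherical lesion phantom
#'
#' Produces a volume equal to `background_level` plus global white noise,
#' with the lesion region set to `lesion_level` plus `h` times a unit-SD
#' band-limited texture field; the mask is the lesion support. Deterministic
#' for a given `(spec, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return List with elements `volume` ([image_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
make_lesion_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  co <- voxel_coords(d, spec$spacing, c(0, 0, 0))
  centre <- vapply(co, function(v) (v[1] + v[length(v)]) / 2, 0)
  dist2 <- outer(outer((co[[1]] - centre[1])^2, (co[[2]] - centre[2])^2, "+"),
                 (co[[3]] - centre[3])^2, "+")
  inside <- dist2 <= spec$lesion_radius^2
  vals <- array(spec$background_level, d)
  vals[inside] <- spec$lesion_level
  with_seed(seed, {
    if (spec$heterogeneity > 0) {
      tex <- smooth_gaussian(array(stats::rnorm(prod(d)), d),
                             spec$texture_scale_mm / spec$spacing)
      s <- stats::sd(tex[inside])
      if (s > 0)
        vals[inside] <- vals[inside] +
          spec$heterogeneity * (tex[inside] - mean(tex[inside])) / s
    }
    if (spec$noise_sigma > 0)
      vals <- vals + array(stats::rnorm(prod(d), sd = spec$noise_sigma), d)
  })
  list(volume = image_volume(vals, spec$spacing, c(0, 0, 0), spec$modality),
       mask = roi_mask(inside, spec$spacing, c(0, 0, 0)))
}

# Unsigned distance (mm) from every voxel centre to the nearest mask-surface
# voxel centre, computed in chunks to bound memory. Surface voxels are
# in-mask voxels with a 6-neighbour outside the mask or the grid.
surface_distance_mm <- function(mask) {
  d <- dim(mask$values)
  m <- mask$values
  surf <- m & !(shift_mask(m, 1L, 1L) & shift_mask(m, 1L, -1L) &
                shift_mask(m, 2L, 1L) & shift_mask(m, 2L, -1L) &
                shift_mask(m, 3L, 1L) & shift_mask(m, 3L, -1L))
  co <- voxel_coords(d, mask$spacing, mask$origin)
  idx <- which(surf, arr.ind = TRUE)
  B <- cbind(co[[1]][idx[, 1]], co[[2]][idx[, 2]], co[[3]][idx[, 3]])
  all_idx <- arrayInd(seq_len(prod(d)), d)
  X <- cbind(co[[1]][all_idx[, 1]], co[[2]][all_idx[, 2]], co[[3]][all_idx[, 3]])
  nb <- nrow(B)
  b2 <- rowSums(B^2)
  out <- numeric(nrow(X))
  step <- max(1L, floor(2e6 / nb))
  for (s in seq(1L, nrow(X), by = step)) {
    e <- min(s + step - 1L, nrow(X))
    Xc <- X[s:e, , drop = FALSE]
    D2 <- outer(rowSums(Xc^2), b2, "+") - 2 * Xc %*% t(B)
    out[s:e] <- sqrt(pmax(apply(D2, 1L, min), 0))
  }
  array(out, d)
}

# Logical-array shift along `axis` by `by` voxels; vacated entries FALSE.
shift_mask <- function(m, axis, by) {
  d <- dim(m)
  idx <- seq_len(d[axis]) - by
  ok <- idx >= 1L & idx <= d[axis]
  out <- array(FALSE, d)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  dst[[axis]] <- which(ok)
  src[[axis]] <- idx[ok]
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Perturb a contour with a smooth random boundary displacement
#'
#' Emulates inter-observer delineation variability: the mask boundary is
#' displaced by a smooth (band-limited Gaussian) random field of RMS
#' amplitude `magnitude_mm`, implemented as a level-set shift of the signed
#' distance to the mask surface. Voxels far from the boundary are unchanged.
#'
#' @param mask A non-empty [roi_mask()].
#' @param magnitude_mm RMS boundary displacement in mm (>= 0; 0 returns the
#'   input unchanged).
#' @param seed Integer seed.
#' @param scale_mm Correlation length of the displacement field (mm).
#' @return A perturbed `roi_mask`.
#' @export
perturb_mask <- function(mask, magnitude_mm, seed, scale_mm = 15) {
  stopifnot(inherits(mask, "roi_mask"))
  if (mask_size(mask) == 0L) stop("mask is empty")
  if (magnitude_mm < 0) stop("'magnitude_mm' must be >= 0")
  if (magnitude_mm == 0) return(mask)
  d <- dim(mask$values)
  dist <- surface_distance_mm(mask)
  signed <- ifelse(mask$values, -dist, dist) +
    ifelse(mask$values, -0.5, 0.5) * mean(mask$spacing)
  field <- with_seed(seed, {
    f <- smooth_gaussian(array(stats::rnorm(prod(d)), d),
                         scale_mm / mask$spacing)
    f / stats::sd(f)
  })
  keep <- signed + magnitude_mm * field <= 0
  if (!any(keep))
    stop("perturbation emptied the mask; reduce 'magnitude_mm'")
  roi_mask(keep, mask$spacing, mask$origin)
}

#' Simulate right-censored exponential survival times
#'
#' Event times are exponential with hazard proportional to `exp(linpred)`
#' (time scale `baseline_scale`, the mean survival at `linpred = 0`, in
#' months). Censoring is independent uniform on `[0, U]` with `U` solved
#' numerically so the expected censored fraction equals `censor_rate`;
#' `censor_rate = 0` yields fully observed data.
#'
#' @param linpred Numeric vector of per-case log-hazard linear predictors.
#' @param baseline_scale Mean survival time (months) at `linpred = 0`.
#' @param censor_rate Target censored fraction in \[0, 1).
#' @param seed Integer seed.
#' @return `data.frame(time, event)` with `time > 0`, `event` in \{0, 1\}.
#' @export
simulate_survival <- function(linpred, baseline_scale = 16,
                              censor_rate = 0.3, seed = 1L) {
  if (censor_rate < 0 || censor_rate >= 1)
    stop("'censor_rate' must be in [0, 1)")
  n <- length(linpred)
  rate <- exp(linpred) / baseline_scale
  with_seed(seed, {
    t_event <- stats::rexp(n, rate)
    if (censor_rate == 0)
      return(data.frame(time = pmax(t_event, 1e-8), event = 1L))
    # expected censored fraction under C ~ U(0, U): mean_i (1 - e^{-r_i U})/(r_i U)
    frac <- function(U) mean((1 - exp(-rate * U)) / (rate * U)) - censor_rate
    hi <- baseline_scale
    while (frac(hi) > 0) hi <- hi * 2
    U <- stats::uniroot(frac, c(1e-8, hi), tol = 1e-8)$root
    cens <- stats::runif(n, 0, U)
    data.frame(time = pmax(pmin(t_event, cens), 1e-8),
               event = as.integer(t_event <= cens))
  })
}

#' Simulate a phantom cohort with a planted prognostic texture effect
#'
#' Each case gets a heterogeneity parameter `h` drawn uniformly from
#' `h_range` and a lesion radius from `radius_range`; the phantom is rendered
#' with [make_lesion_phantom()] and outcomes come from [simulate_survival()]
#' with linear predictor `beta_true * standardize(h)`, so `beta_true` is the
#' log hazard ratio per SD of the texture parameter.
#'
#' @param n Number of cases (>= 2).
#' @param beta_true Log-hazard slope on standardized `h`.
#' @param censor_rate Target censored fraction.
#' @param seed Integer master seed; all case-level randomness is derived
#'   from it via one splitting rule.
#' @param spec Base [phantom_spec()]; per-case `heterogeneity` and
#'   `lesion_radius` override its values.
#' @param h_range,radius_range Uniform sampling intervals for `h` (intensity
#'   units) and the lesion radius (mm).
#' @param baseline_scale Mean survival (months) at the cohort-average `h`.
#' @param render If `FALSE`, skip phantom rendering (outcome-only cohorts
#'   for statistical checks).
#' @return An object of class `simulated_cohort`: list with `cases` (each
#'   with `volume`, `mask`, `h_true`, `time`, `event`), `h`, `outcomes`
#'   (data.frame `case_id`, `time_months`, `event`), `beta_true`, `seed`.
#' @export
simulate_cohort <- function(n, beta_true, censor_rate = 0.3, seed = 1L,
                            spec = phantom_spec(),
                            h_range = c(0.1, 1.5),
                            radius_range = c(12, 20),
                            baseline_scale = 16,
                            render = TRUE) {
  if (n < 2L) stop("'n' must be >= 2")
  seeds <- split_seed(seed, n + 2L)
  draws <- with_seed(seeds[1L], list(
    h = stats::runif(n, h_range[1], h_range[2]),
    r = stats::runif(n, radius_range[1], radius_range[2])))
  h_std <- (draws$h - mean(draws$h)) / stats::sd(draws$h)
  outc <- simulate_survival(beta_true * h_std, baseline_scale, censor_rate,
                            seed = seeds[2L])
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- if (render) {
      si <- spec
      si$heterogeneity <- draws$h[i]
      si$lesion_radius <- draws$r[i]
      make_lesion_phantom(si, seeds[2L + i])
    } else list(volume = NULL, mask = NULL)
    cases[[i]] <- list(volume = ph$volume, mask = ph$mask,
                       h_true = draws$h[i], time = outc$time[i],
                       event = outc$event[i])
  }
  structure(list(cases = cases, h = draws$h,
                 outcomes = data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                                       time_months = outc$time,
                                       event = outc$event),
                 beta_true = beta_true, censor_rate_target = censor_rate,
                 seed = seed),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "<simulated_cohort> n = %d, beta_true = %g, %d events (%.0f%% censored)\n",
    length(x$cases), x$beta_true, sum(x$outcomes$event),
    100 * mean(1 - x$outcomes$event)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Cases are written as paired NIfTI files `case_<id>_img.nii.gz` /
#' `case_<id>_mask.nii.gz` plus an `outcomes.csv` with columns
#' `case_id,time_months,event`.
#'
#' @param cohort A [simulate_cohort()] result with rendered phantoms.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$cases)) {
    cs <- cohort$cases[[i]]
    if (is.null(cs$volume)) stop("cohort was simulated with render = FALSE")
    id <- cohort$outcomes$case_id[i]
    write_volume(cs$volume, file.path(dir, paste0(id, "_img.nii.gz")))
    write_volume(cs$mask, file.path(dir, paste0(id, "_mask.nii.gz")))
  }
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  invisible(dir)
}
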