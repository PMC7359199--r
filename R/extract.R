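#' Extract the full radiomics feature vector for one case
#'
#' Runs the whole preprocessing and evaluation chain on a co-registered
#' volume/mask pair: resampling to the modality's isotropic voxel size,
#' Hounsfield-window restriction of the mask (CT only), fixed-bin-width
#' discretization, shape/intensity/texture evaluation on the original image,
#' the same intensity and texture evaluation on each of the eight
#' undecimated wavelet sub-band maps, and the PET metabolic-tumor-volume
#' features. SUVmax, SUVmean and the ROI volume are returned as auxiliary
#' outputs alongside the catalogue features.
#'
#' @param volume An [image_volume()].
#' @param mask A [roi_mask()] on the same grid.
#' @param config A [default_config()] list (voxel sizes, window, bin widths).
#' @param resample If `FALSE`, the inputs are taken as already isotropic at
#'   the target spacing and used as-is.
#' @return A list of class `feature_vector`: `values` (named numeric vector
#'   over the modality catalogue; `NA` marks features undefined on this
#'   case), `aux` (named vector: `volume_ml`, plus `SUVmax`/`SUVmean` for
#'   PET), `modality`.
#' @export
extract_all <- function(volume, mask, config = default_config(),
                        resample = TRUE) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  modality <- volume$modality
  target <- if (modality == "CT") config$ct_voxel_mm else config$pet_voxel_mm
  bw <- if (modality == "CT") config$ct_bin else config$pet_bin
  if (resample) {
    volume <- resample_isotropic(volume, target)
    mask <- resample_mask(mask, target)
  }
  if (!identical(dim(volume$values), dim(mask$values)))
    stop("volume and mask grids differ after resampling")
  if (modality == "CT")
    mask <- apply_intensity_window(volume, mask,
                                   config$hu_window[1], config$hu_window[2])
  if (mask_size(mask) == 0L) stop("analysis mask is empty")
  inmask <- volume$values[mask$values]
  grid <- discretize_fixed_bin(volume, mask, bw)
  vals <- c(shape_features(mask), intensity_features(inmask),
            texture_features(grid))
  stack <- wavelet_decompose(volume)
  for (b in wavelet_bands()) {
    bmap <- stack[[b]]
    bgrid <- discretize_fixed_bin(bmap, mask, bw)
    bv <- c(intensity_features(bmap[mask$values]), texture_features(bgrid))
    names(bv) <- paste(b, names(bv))
    vals <- c(vals, bv)
  }
  voxvol_ml <- prod(volume$spacing) / 1000
  aux <- c(volume_ml = mask_size(mask) * voxvol_ml)
  if (modality == "PET") {
    vals <- c(vals, mtv_features(inmask, voxvol_ml))
    aux <- c(aux, SUVmax = max(inmask), SUVmean = mean(inmask))
  }
  cat_names <- build_catalogue(modality)$name
  stopifnot(identical(names(vals), cat_names))
  structure(list(values = vals, aux = aux, modality = modality,
                 catalogue_version = as.character(
                   utils::packageVersion("pleuradiomics"))),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s, %d features (%d missing)\n", x$modality,
              length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Extract features for every case of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] result with rendered phantoms.
#' @param config A [default_config()] list.
#' @param resample Passed to [extract_all()]; cohort phantoms are rendered
#'   isotropic at the target spacing, so the default skips resampling.
#' @return A `data.frame` of cases x (catalogue features + auxiliary
#'   columns), row names = case ids; column names are catalogue names.
#' @export
extract_cohort <- function(cohort, config = default_config(),
                           resample = FALSE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  rows <- lapply(cohort$cases, function(cs) {
    fv <- extract_all(cs$volume, cs$mask, config, resample = resample)
    c(fv$values, fv$aux)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- cohort$outcomes$case_id
  out
}

#' Write a feature table as CSV
#'
#' One row per case, one column per catalogue feature, missing values as
#' empty cells; a `case_id` column leads.
#'
#' @param features A data.frame as from [extract_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  out <- cbind(case_id = rownames(features), features)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
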