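intensity_names <- function() names(intensity_features(c(0, 1)))
shape_names <- function() {
  c("shape voxel volume", "shape mesh volume", "shape surface area",
    "shape surface to volume ratio", "shape sphericity",
    "shape compactness 1", "shape compactness 2",
    "shape spherical disproportion", "shape asphericity",
    "shape centre of mass shift", "shape maximum 3D diameter",
    "shape major axis length", "shape minor axis length",
    "shape least axis length", "shape elongation", "shape flatness",
    "shape volume density aabb", "shape area density aabb")
}
texture_names <- function() {
  c(paste("GLCM", glcm_base_names),
    paste("GLCM", glcm_base_names, "merged"),
    ij_feature_names("GLRLM", "run", TRUE),
    paste(ij_feature_names("GLRLM", "run", TRUE), "merged"),
    ij_feature_names("GLSZM", "zone", TRUE),
    ij_feature_names("GLDZM", "distance", TRUE),
    paste("NGTDM", c("coarseness", "contrast", "busyness", "complexity",
                     "strength")),
    c(ij_feature_names("NGLDM", "dependence", FALSE),
      "NGLDM dependence count energy"))
}

wavelet_bands <- function() c("LLL", "LLH", "LHL", "LHH",
                              "HLL", "HLH", "HHL", "HHH")

#' Build the feature catalogue for a modality
#'
#' The full, ordered feature list: 18 shape + 17 intensity + 137 texture
#' features on the original image, the same 17 + 137 on each of the eight
#' wavelet sub-band maps (names prefixed with the band tag, e.g.
#' `"HLH intensity range"`), and — for PET only — the 6 metabolic-tumor-
#' volume features. Totals: 1404 entries for CT, 1410 for PET.
#'
#' @param modality `"CT"` or `"PET"`.
#' @return A `data.frame` with columns `name`, `family` (`shape`,
#'   `intensity`, `texture`, `wavelet`, `mtv`), `band` (`none` or the
#'   sub-band tag), `modality`.
#' @export
build_catalogue <- function(modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  base <- data.frame(
    name = c(shape_names(), intensity_names(), texture_names()),
    family = c(rep("shape", 18L), rep("intensity", 17L),
               rep("texture", 137L)),
    band = "none", stringsAsFactors = FALSE)
  wav <- do.call(rbind, lapply(wavelet_bands(), function(b)
    data.frame(name = paste(b, c(intensity_names(), texture_names())),
               family = "wavelet", band = b, stringsAsFactors = FALSE)))
  cat_df <- rbind(base, wav)
  if (modality == "PET")
    cat_df <- rbind(cat_df,
                    data.frame(name = sprintf("MTV%d", seq(20, 70, by = 10)),
                               family = "mtv", band = "none",
                               stringsAsFactors = FALSE))
  cat_df$modality <- modality
  stopifnot(!anyDuplicated(cat_df$name))
  cat_df
}

#' Write a catalogue as JSON
#'
#' @param cat_df A [build_catalogue()] result.
#' @param path Output path for `catalogue.json`.
#' @return `path`, invisibly.
#' @export
write_catalogue_json <- function(cat_df, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write catalogue JSON")
  jsonlite::write_json(cat_df, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
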