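#' Extraction configuration
#'
#' Settings that define the radiomic panel: isotropic target voxel size
#' (resampling is skipped when the input already sits on that grid),
#' fixed bin width for gray-level discretization, and the wavelet kernel for
#' the eight-band decomposition. Each wavelet band is re-discretized with the
#' same bin width against its own masked minimum.
#'
#' @param voxel_size_mm isotropic target voxel size (mm); `NULL` disables
#'   resampling.
#' @param bin_width fixed bin width in intensity units.
#' @param wavelet wavelet kernel, see [wavelet_decompose()].
#' @param first_order_rebinned unused placeholder kept for config
#'   round-tripping; first-order Entropy/Uniformity always use the bin width.
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(voxel_size_mm = 2, bin_width = 25,
                              wavelet = "coif1", first_order_rebinned = TRUE) {
  stopifnot(bin_width > 0)
  structure(list(voxel_size_mm = voxel_size_mm, bin_width = bin_width,
                 wavelet = wavelet, first_order_rebinned = first_order_rebinned),
            class = "extraction_config")
}

feature_classes <- function() c("shape", "firstorder", "glcm", "gldm",
                                "glrlm", "glszm", "ngtdm")

class_feature_names <- function(cls) {
  switch(cls,
         shape = shape_feature_names(),
         firstorder = firstorder_feature_names(),
         glcm = glcm_feature_names(),
         gldm = gldm_feature_names(),
         glrlm = glrlm_feature_names(),
         glszm = glszm_feature_names(),
         ngtdm = ngtdm_feature_names())
}

#' Names and manifest of the 841-feature panel
#'
#' The panel is 105 original-image features (13 shape + 92 intensity/texture)
#' plus the 92 non-shape features on each of the 8 wavelet sub-bands
#' (8 x 92 = 736). Names follow the `filter_class_Feature` scheme, e.g.
#' `original_glcm_Contrast` or `wavelet_HLH_glszm_SmallAreaEmphasis`.
#'
#' @return `panel_feature_names()`: character vector of length 841.
#'   `feature_manifest()`: tibble with columns `name`, `filter`,
#'   `feature_class`, `feature`.
#' @export
panel_feature_names <- function() feature_manifest()$name

#' @rdname panel_feature_names
#' @export
feature_manifest <- function() {
  rows <- list()
  for (cls in feature_classes())
    rows[[length(rows) + 1L]] <- tibble::tibble(
      filter = "original", feature_class = cls, feature = class_feature_names(cls))
  for (b in band_labels())
    for (cls in setdiff(feature_classes(), "shape"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        filter = paste0("wavelet_", b), feature_class = cls,
        feature = class_feature_names(cls))
  out <- dplyr::bind_rows(rows)
  out$name <- paste(out$filter, out$feature_class, out$feature, sep = "_")
  out[, c("name", "filter", "feature_class", "feature")]
}

# all non-shape features of one image (intensities + discretized texture)
non_shape_features <- function(vol, msk, bin_width, spacing_mm) {
  roi <- discretize(vol, msk, bin_width)
  c(setNames(firstorder_features(vol, msk, bin_width, spacing_mm),
             paste0("firstorder_", firstorder_feature_names())),
    setNames(glcm_features(roi), paste0("glcm_", glcm_feature_names())),
    setNames(gldm_features(roi), paste0("gldm_", gldm_feature_names())),
    setNames(glrlm_features(roi), paste0("glrlm_", glrlm_feature_names())),
    setNames(glszm_features(roi), paste0("glszm_", glszm_feature_names())),
    setNames(ngtdm_features(roi), paste0("ngtdm_", ngtdm_feature_names())))
}

#' Extract the full 841-feature radiomic panel from one volume
#'
#' Optionally resamples volume and mask to the isotropic grid of the config,
#' computes the 105 original-image features, decomposes the (resampled)
#' volume into 8 undecimated wavelet sub-bands, and computes the 92 non-shape
#' features on each band (rebinned against the band's own masked minimum).
#' Failed feature classes propagate as `NA` values, never dropped columns.
#'
#' @param volume,mask `image_volume` objects (or 3-D arrays at unit spacing).
#' @param config an [extraction_config()].
#' @param patient_id optional id attached to the result.
#' @return A one-row tibble: `patient_id` plus 841 feature columns in the
#'   deterministic panel order of [panel_feature_names()].
#' @export
extract_features <- function(volume, mask, config = extraction_config(),
                             patient_id = NA_character_) {
  volume <- as_image_volume(volume)
  mask <- as_image_volume(mask, volume$spacing_mm, volume$origin)
  if (!is.null(config$voxel_size_mm)) {
    tgt <- rep(config$voxel_size_mm, length.out = 3)
    if (any(abs(volume$spacing_mm - tgt) > 1e-9)) {
      rs <- resample_isotropic(volume, mask, tgt, patient_id)
      volume <- rs$volume; mask <- rs$mask
    }
  }
  sp <- volume$spacing_mm
  vol <- volume$data; msk <- mask$data
  bw <- config$bin_width

  orig <- non_shape_features(vol, msk, bw, sp)
  out <- c(
    setNames(shape_features(msk, sp),
             paste0("original_shape_", shape_feature_names())),
    setNames(orig, paste0("original_", names(orig))))
  bands <- wavelet_decompose(vol, config$wavelet)
  for (b in band_labels()) {
    fb <- non_shape_features(bands[[b]], msk, bw, sp)
    out <- c(out, setNames(fb, paste0("wavelet_", b, "_", names(fb))))
  }
  stopifnot(identical(names(out), panel_feature_names()))
  tibble::as_tibble(c(list(patient_id = patient_id), as.list(out)))
}

#' Extract the panel for every patient of a phantom cohort
#'
#' @param cohort a `phantom_cohort` from [generate_cohort()].
#' @param config an [extraction_config()].
#' @param verbose print progress every 25 patients.
#' @return Tibble with `patient_id` and 841 feature columns (a feature
#'   table); clinical and outcome columns stay in the cohort tables.
#' @export
extract_cohort <- function(cohort, config = extraction_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  n <- length(cohort$volumes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- extract_features(
      image_volume(cohort$volumes[[i]], cohort$spec$voxel_size_mm),
      image_volume(cohort$masks[[i]], cohort$spec$voxel_size_mm),
      config, patient_id = cohort$clinical$patient_id[i])
    if (verbose && i %% 25 == 0) message("extracted ", i, "/", n)
  }
  dplyr::bind_rows(rows)
}
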