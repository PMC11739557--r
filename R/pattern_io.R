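#' Persist a covariance pattern
#'
#' Writes the voxel weights as a NIfTI-1 volume (devectorized into the mask),
#' the mask and the reference offset as companion NIfTI volumes, and a JSON
#' sidecar holding the selected components, logistic coefficients,
#' normalization factor and derivation control score statistics.
#'
#' @param pattern a `cov_pattern`.
#' @param prefix file path prefix; files `<prefix>_weights.nii.gz`,
#'   `<prefix>_mask.nii.gz`, `<prefix>_offset.nii.gz` and `<prefix>.json`
#'   are produced.
#' @return `prefix`, invisibly.
#' @export
save_pattern <- function(pattern, prefix) {
  stopifnot(inherits(pattern, "cov_pattern"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  write_weight_map(pattern$weights, pattern$mask,
                   paste0(prefix, "_weights.nii.gz"))
  write_volume(pattern$mask, paste0(prefix, "_mask.nii.gz"))
  write_weight_map(pattern$reference_offset, pattern$mask,
                   paste0(prefix, "_offset.nii.gz"))
  jsonlite::write_json(list(selected_pcs = pattern$selected_pcs,
                            coefficients = pattern$coefficients,
                            norm_factor = pattern$norm_factor,
                            control = pattern$control,
                            derivation_score_stats = pattern$derivation_score_stats),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Load a persisted covariance pattern
#'
#' @param prefix the prefix given to [save_pattern()].
#' @return A `cov_pattern`.
#' @export
load_pattern <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mask <- read_mask(paste0(prefix, "_mask.nii.gz"))
  wv <- RNifti::readNifti(paste0(prefix, "_weights.nii.gz"))
  ov <- RNifti::readNifti(paste0(prefix, "_offset.nii.gz"))
  structure(list(weights = as.array(wv)[mask$voxel_order],
                 mask = mask,
                 selected_pcs = as.integer(meta$selected_pcs),
                 coefficients = as.numeric(meta$coefficients),
                 norm_factor = meta$norm_factor,
                 reference_offset = as.array(ov)[mask$voxel_order],
                 derivation_score_stats = as.list(meta$derivation_score_stats),
                 control = meta$control),
            class = "cov_pattern")
}
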