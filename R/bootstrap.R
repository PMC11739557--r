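#' Bootstrap validation of pattern topography
#'
#' Resamples subjects with replacement within each group (group sizes
#' preserved), reruns the full derivation on every resample -- double
#' centering recomputed on the resample, PCA, variance-target prefix
#' selection, and the logistic combination with the point estimate's subset
#' size as the search space -- sign-aligns each resampled pattern to the point
#' estimate, and forms per-voxel percentile confidence intervals of the voxel
#' weights. Voxels whose interval contains zero are zeroed in the thresholded
#' pattern; the study operating point is 1000 iterations at a 95% interval.
#'
#' @param scans list of aligned `pet_volume` objects (derivation sample).
#' @param labels group label per scan.
#' @param mask common analysis `pet_mask`; built from the scans when `NULL`.
#' @param n_iterations bootstrap iterations (>= 2).
#' @param ci_level confidence level in (0, 1).
#' @param seed integer seed controlling the resampling.
#' @param control control-group label.
#' @param variance_target,max_subset_size,screen_p derivation settings, as
#'   in [derive_pattern()].
#' @param subset_mode `"fixed_size"` reruns the logistic search restricted to
#'   the point estimate's subset size (default); `"frozen"` reuses the point
#'   estimate's component indices without searching; `"full"` reruns the
#'   unrestricted search.
#' @param max_retries redraw budget for degenerate resamples (a group
#'   collapsing to a single distinct subject, or rank-0 residuals).
#' @param keep_weights store the voxels-by-iterations weight matrix (needed
#'   for re-thresholding and oracle checks).
#' @param .resample internal override of the within-group resampler, a
#'   `function(idx)` returning indices; used to exercise degenerate cases.
#' @return An `ssm_bootstrap` object with the point-estimate derivation,
#'   per-voxel `voxel_lower`/`voxel_upper`, `thresholded_weights`,
#'   `n_surviving`, and (optionally) the iteration `weights` matrix.
#' @export
bootstrap_pattern <- function(scans, labels, mask = NULL,
                              n_iterations = 1000L, ci_level = 0.95,
                              seed = 1L, control = "HC",
                              variance_target = 0.5, max_subset_size = 4L,
                              screen_p = 0.05,
                              subset_mode = c("fixed_size", "frozen", "full"),
                              max_retries = 100L, keep_weights = TRUE,
                              mask_fraction = 0.35,
                              .resample = NULL) {
  subset_mode <- match.arg(subset_mode)
  if (n_iterations < 2L) stop("n_iterations must be >= 2")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  if (is.null(mask)) mask <- cohort_mask(scans, fraction = mask_fraction)
  prof <- build_profiles(scans, mask, labels, control = control)
  point <- derive_from_profiles(prof, variance_target = variance_target,
                                max_subset_size = max_subset_size,
                                screen_p = screen_p)
  w0 <- point$pattern$weights
  size0 <- length(point$fit$selected_pcs)
  groups <- split(seq_along(labels), labels)
  set.seed(seed)
  W <- matrix(NA_real_, length(w0), n_iterations)
  retries <- 0L
  it <- 1L
  while (it <= n_iterations) {
    idx <- unlist(lapply(groups, function(g) {
      if (is.null(.resample)) sample(g, length(g), replace = TRUE)
      else .resample(g)
    }), use.names = FALSE)
    wi <- tryCatch({
      degenerate <- any(vapply(split(idx, labels[idx]),
                               function(v) length(unique(v)) < 2L, logical(1)))
      if (degenerate) stop("degenerate resample")
      bprof <- new_profiles(prof$values[idx, , drop = FALSE], state = "log",
                            subject_ids = prof$subject_ids[idx],
                            group_labels = prof$group_labels[idx],
                            mask = mask, control = control)
      der <- switch(subset_mode,
        fixed_size = derive_from_profiles(bprof, variance_target = variance_target,
                                          exact_size = size0,
                                          screen_p = screen_p),
        full = derive_from_profiles(bprof, variance_target = variance_target,
                                    max_subset_size = max_subset_size,
                                    screen_p = screen_p),
        frozen = {
          res <- double_center(bprof)
          basis <- run_pca(res)
          keep <- point$fit$selected_pcs[point$fit$selected_pcs <=
                                           ncol(basis$voxel_components)]
          if (length(keep) < 1L) stop("degenerate resample")
          fit <- fit_logistic_combination(basis, keep, exact_size = length(keep))
          list(pattern = build_pattern(basis, fit$selected_pcs, fit$coefficients))
        })
      der$pattern$weights
    }, error = function(e) NULL)
    if (is.null(wi)) {
      retries <- retries + 1L
      if (retries > max_retries)
        stop("bootstrap retry cap exceeded (", max_retries,
             " degenerate resamples)")
      next
    }
    if (stats::cor(wi, w0) < 0) wi <- -wi   # sign-align to the point estimate
    W[, it] <- wi
    it <- it + 1L
  }
  res <- structure(list(point = point, n_iterations = n_iterations,
                        ci_level = ci_level, seed = seed,
                        subset_mode = subset_mode, retries = retries,
                        weights = W, mask = mask),
                   class = "ssm_bootstrap")
  res <- bootstrap_threshold(res, ci_level)
  if (!keep_weights) res$weights <- NULL
  res
}

#' Re-threshold a bootstrap result at a different confidence level
#'
#' Recomputes the per-voxel percentile interval and the thresholded pattern
#' from the stored iteration weights, without rerunning the resampling.
#'
#' @param res an `ssm_bootstrap` with stored `weights`.
#' @param ci_level confidence level in (0, 1).
#' @return The updated `ssm_bootstrap`.
#' @export
bootstrap_threshold <- function(res, ci_level) {
  stopifnot(inherits(res, "ssm_bootstrap"))
  if (is.null(res$weights))
    stop("iteration weights were not stored; rerun with keep_weights = TRUE")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  alpha <- (1 - ci_level) / 2
  qs <- apply(res$weights, 1L, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  res$ci_level <- ci_level
  res$voxel_lower <- qs[1L, ]
  res$voxel_upper <- qs[2L, ]
  w0 <- res$point$pattern$weights
  surviving <- res$voxel_lower > 0 | res$voxel_upper < 0
  tw <- ifelse(surviving, w0, 0)
  res$thresholded_weights <- tw
  res$n_surviving <- sum(tw != 0)
  res
}

#' @export
print.ssm_bootstrap <- function(x, ...) {
  cat(sprintf("<ssm_bootstrap> %d iterations @ %.0f%% CI (seed %d): %d of %d voxels survive\n",
              x$n_iterations, 100 * x$ci_level, x$seed, x$n_surviving,
              length(x$point$pattern$weights)))
  invisible(x)
}

#' Write a bootstrap-thresholded pattern to disk
#'
#' NIfTI-1 weight volume plus a JSON sidecar recording iterations, CI level,
#' seed and surviving voxel count.
#'
#' @param res an `ssm_bootstrap`.
#' @param path_nii output NIfTI path.
#' @param path_json output JSON sidecar path (defaults next to `path_nii`).
#' @return `path_nii`, invisibly.
#' @export
write_bootstrap <- function(res, path_nii,
                            path_json = sub("\\.nii(\\.gz)?$", ".json", path_nii)) {
  write_weight_map(res$thresholded_weights, res$mask, path_nii)
  jsonlite::write_json(list(n_iterations = res$n_iterations,
                            ci_level = res$ci_level, seed = res$seed,
                            subset_mode = res$subset_mode,
                            n_surviving = res$n_surviving),
                       path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_nii)
}
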