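#' Voxel-weight correlation between two patterns
#'
#' Quantifies topographic overlap: the voxel weights of both patterns are
#' devectorized onto their (common) grid, the voxels retained are those inside
#' both masks and -- by default -- non-zero in both patterns, the two weight
#' vectors are formed in a fixed voxel order, and their Pearson product-moment
#' correlation is computed. A union variant (voxels non-zero in either
#' pattern, zeros kept) is available behind `support`.
#'
#' The returned p-value is the ordinary two-sided correlation test and is
#' flagged: voxel weights are spatially autocorrelated, so it is
#' anti-conservative and should not be read at face value.
#'
#' @param p1,p2 `cov_pattern` objects on the same grid.
#' @param support `"intersection"` (default) or `"union"` of the non-zero
#'   supports within the common mask.
#' @return List with `r`, `r_squared`, `n_voxels_used`, `p_value`, and
#'   `autocorrelation_warning = TRUE`.
#' @export
voxelweight_correlation <- function(p1, p2,
                                    support = c("intersection", "union")) {
  support <- match.arg(support)
  stopifnot(inherits(p1, "cov_pattern"), inherits(p2, "cov_pattern"))
  if (!volumes_aligned(dim(p1$mask$data), p1$mask$affine,
                       dim(p2$mask$data), p2$mask$affine))
    stop("patterns are not on a common grid")
  a1 <- array(0, dim = dim(p1$mask$data)); a1[p1$mask$voxel_order] <- p1$weights
  a2 <- array(0, dim = dim(p2$mask$data)); a2[p2$mask$voxel_order] <- p2$weights
  common <- p1$mask$data & p2$mask$data
  if (!any(common)) stop("the two masks have an empty intersection")
  keep <- if (support == "intersection") {
    common & a1 != 0 & a2 != 0
  } else {
    common & (a1 != 0 | a2 != 0)
  }
  idx <- which(keep)
  if (length(idx) < 3L)
    stop("fewer than 3 common voxels (", length(idx), "); correlation undefined")
  x <- a1[idx]; y <- a2[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a weight vector over the common support")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       n_voxels_used = length(idx), p_value = ct$p.value,
       autocorrelation_warning = TRUE)
}

#' Correlation of subject scores between two patterns
#'
#' Pearson correlation of the two patterns' z-transformed expression scores
#' across the same subjects, with a two-sided p-value.
#'
#' @param scores1,scores2 `score_table`s (after [z_transform()]) covering the
#'   same subjects.
#' @return List with `r`, `p_value`, and `n`.
#' @export
score_correlation <- function(scores1, scores2) {
  for (s in list(scores1, scores2))
    if (!all(c("subject_id", "z_score") %in% names(s)))
      stop("score tables must carry subject_id and z_score columns")
  if (nrow(scores1) != nrow(scores2) ||
      !setequal(scores1$subject_id, scores2$subject_id))
    stop("the two score tables must cover the same subjects")
  m <- match(scores1$subject_id, scores2$subject_id)
  if (nrow(scores1) < 3L) stop("need at least 3 subjects")
  ct <- stats::cor.test(scores1$z_score, scores2$z_score[m],
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(scores1))
}
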