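#' Pattern-expression score of a single scan
#'
#' Projects one scan onto a covariance pattern: the masked intensities are
#' log-transformed, the subject mean is removed (eliminating any global
#' scaling factor), the pattern's stored control-mean reference offset is
#' subtracted, and the residual profile is dotted with the voxel weights. The
#' computation involves no other scan, so scores are fully prospective:
#' scoring scans one at a time equals batch scoring, and derivation subjects
#' rescored this way reproduce their derivation scores exactly.
#'
#' @param v a `pet_volume` aligned with the pattern's mask, strictly positive
#'   on the mask.
#' @param pattern a `cov_pattern`.
#' @return The raw pattern-expression score (a single number).
#' @export
score_scan <- function(v, pattern) {
  stopifnot(inherits(pattern, "cov_pattern"))
  x <- vectorize(v, pattern$mask)
  if (any(x <= 0))
    stop("non-positive masked voxel in scan ", v$id %||% "unnamed",
         ": cannot log-transform")
  lx <- log(x)
  resid <- lx - mean(lx) - pattern$reference_offset
  sum(resid * pattern$weights)
}

#' Score a set of scans against a pattern
#'
#' @param scans list of `pet_volume` objects.
#' @param pattern a `cov_pattern`.
#' @param labels group label per scan.
#' @param subject_ids optional ids; defaults to the scans' own ids.
#' @return A `score_table` data frame with columns `subject_id`, `group`,
#'   `raw_score` (and `z_score` after [z_transform()]).
#' @export
score_cohort <- function(scans, pattern, labels,
                         subject_ids = NULL) {
  if (length(scans) != length(labels)) stop("need one label per scan")
  if (is.null(subject_ids))
    subject_ids <- vapply(seq_along(scans),
                          function(s) scans[[s]]$id %||% paste0("subj_", s),
                          character(1))
  raw <- vapply(scans, score_scan, numeric(1), pattern = pattern)
  out <- data.frame(subject_id = subject_ids, group = as.character(labels),
                    raw_score = raw, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Z-transform pattern-expression scores against a reference group
#'
#' Standardizes raw scores so the reference (control) group has mean 0 and
#' SD 1: `z = (raw - mean_ref) / sd_ref`, with the SD using the n-1
#' denominator. When `reference_stats` is supplied (e.g. the
#' `derivation_score_stats` of a `cov_pattern`), prospective cohorts are
#' z-scored against the derivation controls instead of any group in the
#' table -- the handling used when no independent control cohort exists.
#'
#' @param scores a `score_table` from [score_cohort()].
#' @param reference label of the reference group within `scores`.
#' @param reference_stats optional list with `mean` and `sd` overriding the
#'   in-table reference group.
#' @return The `score_table` with a `z_score` column and attributes
#'   `reference_mean`/`reference_sd`.
#' @export
z_transform <- function(scores, reference = "HC", reference_stats = NULL) {
  stopifnot(inherits(scores, "data.frame"), "raw_score" %in% names(scores))
  if (is.null(reference_stats)) {
    ref <- scores$raw_score[scores$group == reference]
    if (length(ref) < 2L)
      stop("need at least 2 reference subjects labelled '", reference, "'")
    m <- mean(ref); s <- stats::sd(ref)
  } else {
    m <- reference_stats$mean; s <- reference_stats$sd
  }
  if (!is.finite(s) || s <= 0) stop("reference group has zero score variance")
  scores$z_score <- (scores$raw_score - m) / s
  attr(scores, "reference_mean") <- m
  attr(scores, "reference_sd") <- s
  class(scores) <- unique(c("score_table", class(scores)))
  scores
}

#' Write a score table as CSV
#'
#' @param scores a `score_table`.
#' @param path output CSV path.
#' @param pattern_id identifier recorded in the `pattern_id` column.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, pattern_id = "pattern") {
  out <- as.data.frame(scores)
  out$pattern_id <- pattern_id
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
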