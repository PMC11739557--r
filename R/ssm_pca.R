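#' Build log-intensity subject profiles
#'
#' Vectorizes each aligned scan over the analysis mask and takes the natural
#' log, giving the subjects-by-voxels profile matrix the scaled subprofile
#' model operates on. A per-subject multiplicative global scale becomes an
#' additive row constant here, which the subsequent subject-mean removal
#' eliminates exactly.
#'
#' @param scans list of aligned `pet_volume` objects, strictly positive on the
#'   mask.
#' @param mask the common `pet_mask`.
#' @param labels character group label per scan.
#' @param control label identifying the reference (control) group.
#' @return An `ssm_profiles` object, `state = "log"`.
#' @export
build_profiles <- function(scans, mask, labels, control = "HC") {
  if (length(scans) != length(labels))
    stop("need one group label per scan")
  if (!any(labels == control))
    stop("no scans labelled as control group '", control, "'")
  n <- length(scans)
  X <- matrix(NA_real_, n, mask$n_voxels)
  ids <- character(n)
  for (s in seq_len(n)) {
    x <- vectorize(scans[[s]], mask)
    if (any(x <= 0)) {
      bad <- which(x <= 0)[1L]
      stop("non-positive masked voxel in subject ", s,
           " (", scans[[s]]$id %||% "unnamed", "), mask voxel ", bad,
           ": log transform undefined")
    }
    X[s, ] <- log(x)
    ids[s] <- scans[[s]]$id %||% paste0("subj_", s)
  }
  new_profiles(X, state = "log", subject_ids = ids,
               group_labels = as.character(labels), mask = mask,
               control = control)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_profiles <- function(values, state, subject_ids, group_labels, mask,
                         control, reference_offset = NULL) {
  structure(list(values = values, state = state, subject_ids = subject_ids,
                 group_labels = group_labels, mask = mask, control = control,
                 reference_offset = reference_offset),
            class = "ssm_profiles")
}

#' @export
print.ssm_profiles <- function(x, ...) {
  cat(sprintf("<ssm_profiles> %d subjects x %d voxels, state = %s\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Double centering of log profiles
#'
#' First removes each subject's mean across voxels (eliminating the global
#' scaling factor exactly), then removes the voxel-wise mean over control
#' subjects from every row. The retained control-mean vector is the
#' `reference_offset` later used to score new scans identically to the
#' derivation sample. After the operation every row mean is zero and the
#' control rows have zero column means.
#'
#' @param p an `ssm_profiles` object with `state = "log"`.
#' @return An `ssm_profiles` object with `state = "residual"` and the
#'   `reference_offset` field populated.
#' @export
double_center <- function(p) {
  stopifnot(inherits(p, "ssm_profiles"))
  if (p$state != "log") stop("double_center expects state = 'log' profiles")
  ctrl <- p$group_labels == p$control
  if (!any(ctrl)) stop("no control subjects; cannot form the reference offset")
  X <- p$values - rowMeans(p$values)
  offset <- colMeans(X[ctrl, , drop = FALSE])
  X <- sweep(X, 2L, offset)
  new_profiles(X, state = "residual", subject_ids = p$subject_ids,
               group_labels = p$group_labels, mask = p$mask,
               control = p$control, reference_offset = offset)
}

#' Principal component analysis of residual profiles
#'
#' Eigen-decomposition of the subjects-by-subjects covariance of the residual
#' matrix, with eigenvectors mapped back to voxel space and normalized to unit
#' norm -- the standard computational route when voxels far outnumber
#' subjects, numerically identical to a dense voxel-space SVD. Subject scores
#' are the projections of each residual row onto each voxel component;
#' variance fractions come from the eigenvalues over their total. Each
#' component is oriented so the patient-group mean score is at least the
#' control-group mean score, fixing the arbitrary PCA sign in the direction of
#' elevated patient expression.
#'
#' @param p an `ssm_profiles` object with `state = "residual"`.
#' @param rank_tol relative eigenvalue threshold below which components are
#'   dropped as numerically null.
#' @return An `ssm_pca` object with `voxel_components` (voxels x K,
#'   orthonormal), `subject_scores` (subjects x K), `variance_fractions`, and
#'   the profile metadata.
#' @export
run_pca <- function(p, rank_tol = 1e-10) {
  stopifnot(inherits(p, "ssm_profiles"))
  if (p$state != "residual") stop("run_pca expects state = 'residual' profiles")
  Y <- p$values
  if (nrow(Y) < 3L) stop("PCA needs at least 3 subjects")
  G <- tcrossprod(Y)                      # subjects x subjects
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > rank_tol * max(eg$values, 0)
  if (max(eg$values, 0) <= 0 || !any(pos))
    stop("residual matrix has rank 0 (all residuals zero); PCA undefined")
  lam <- eg$values[pos]
  U <- eg$vectors[, pos, drop = FALSE]
  V <- crossprod(Y, U)                    # voxels x K, columns prop. to sqrt(lam)
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  scores <- Y %*% V
  # sign convention: patient mean score >= control mean score
  ctrl <- p$group_labels == p$control
  flip <- colMeans(scores[!ctrl, , drop = FALSE]) <
    colMeans(scores[ctrl, , drop = FALSE])
  if (any(flip)) {
    V[, flip] <- -V[, flip]
    scores[, flip] <- -scores[, flip]
  }
  structure(list(voxel_components = V, subject_scores = scores,
                 variance_fractions = lam / sum(lam),
                 subject_ids = p$subject_ids, group_labels = p$group_labels,
                 control = p$control, mask = p$mask,
                 reference_offset = p$reference_offset),
            class = "ssm_pca")
}

#' @export
print.ssm_pca <- function(x, ...) {
  k <- length(x$variance_fractions)
  cat(sprintf("<ssm_pca> %d subjects, %d components; top fractions: %s\n",
              nrow(x$subject_scores), k,
              paste(sprintf("%.1f%%", 100 * utils::head(x$variance_fractions, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Select the leading components covering a variance target
#'
#' Returns the shortest prefix of principal components whose cumulative
#' variance fraction reaches `variance_target` (default: the top 50% of
#' variance).
#'
#' @param b an `ssm_pca` object.
#' @param variance_target cumulative variance fraction in (0, 1).
#' @return Integer vector of component indices `1:m`.
#' @export
select_components <- function(b, variance_target = 0.5) {
  stopifnot(inherits(b, "ssm_pca"))
  if (variance_target <= 0 || variance_target >= 1)
    stop("variance_target must lie strictly between 0 and 1")
  cum <- cumsum(b$variance_fractions)
  m <- which(cum >= variance_target - 1e-12)[1L]
  if (is.na(m)) m <- length(cum)  # fractions sum to 1 up to round-off
  seq_len(m)
}

#' Logistic-regression combination of principal components
#'
#' Searches subsets of the candidate components (exhaustively, up to
#' `max_subset_size`) for the logistic model of group membership on component
#' scores with minimum AIC -- the "best discriminating" combination. The
#' selected subset need not be contiguous. If the winning unpenalized fit is
#' separated (fitted probabilities at 0/1), the returned coefficients come
#' from a ridge-penalized refit with a fixed small penalty so they stay
#' finite; the selection itself is by AIC of the unpenalized fits.
#'
#' Before the subset search, candidates are screened for an individual
#' group-score difference (Welch t-test, `p < screen_p`); components with no
#' marginal group association are excluded, and if none passes the screen the
#' single most associated component is retained. The screen guards the AIC
#' against a degeneracy of strong effects: a near-separating disease
#' component plus any noise component can separate the groups completely
#' in-sample, and a completely separated logistic fit has deviance near zero,
#' so an unscreened AIC systematically prefers such overfit mixtures. Set
#' `screen_p = 1` to disable the screen.
#'
#' @param b an `ssm_pca` object.
#' @param candidate_pcs indices of candidate components (e.g. from
#'   [select_components()]).
#' @param labels optional group labels (defaults to those stored in `b`).
#' @param control control-group label.
#' @param max_subset_size largest subset searched (default 4).
#' @param exact_size if not `NULL`, search only subsets of exactly this size
#'   (used by the bootstrap to hold the point estimate's subset size fixed).
#' @param screen_p marginal-association screen level; 1 disables.
#' @param ridge_lambda fixed ridge penalty for the separation fallback.
#' @return List with `selected_pcs`, `coefficients` (slopes, intercept
#'   excluded), `aic`, `separated` (logical), and `screened_pcs` (candidates
#'   that survived the screen).
#' @export
fit_logistic_combination <- function(b, candidate_pcs, labels = NULL,
                                     control = NULL, max_subset_size = 4L,
                                     exact_size = NULL, screen_p = 0.05,
                                     ridge_lambda = 1e-3) {
  stopifnot(inherits(b, "ssm_pca"))
  labels <- labels %||% b$group_labels
  control <- control %||% b$control
  if (length(candidate_pcs) < 1L) stop("candidate_pcs must be non-empty")
  y <- as.integer(labels != control)
  if (length(unique(y)) < 2L) stop("both groups must be present")
  if (screen_p < 1) {
    pv <- apply(b$subject_scores[, candidate_pcs, drop = FALSE], 2L,
                function(s) stats::t.test(s[y == 1L], s[y == 0L])$p.value)
    keep <- pv < screen_p
    if (!any(keep)) keep <- seq_along(pv) == which.min(pv)
    candidate_pcs <- candidate_pcs[keep]
  }
  S <- b$subject_scores[, candidate_pcs, drop = FALSE]
  sizes <- if (is.null(exact_size)) {
    seq_len(min(max_subset_size, length(candidate_pcs)))
  } else {
    min(exact_size, length(candidate_pcs))
  }
  best <- NULL
  for (sz in sizes) {
    subsets <- utils::combn(seq_along(candidate_pcs), sz, simplify = FALSE)
    for (sub in subsets) {
      Xs <- S[, sub, drop = FALSE]
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, Xs), y, family = stats::binomial()))
      aic <- fit$deviance + 2 * (sz + 1L)
      if (is.null(best) || aic < best$aic - 1e-12) {
        mu <- fit$fitted.values
        best <- list(sub = sub, aic = aic,
                     coef = fit$coefficients[-1L],
                     separated = !fit$converged ||
                       any(mu < 1e-8 | mu > 1 - 1e-8))
      }
    }
  }
  if (is.null(best)) stop("logistic subset search found no fit")
  if (best$separated) {
    beta <- ridge_logistic(S[, best$sub, drop = FALSE], y, lambda = ridge_lambda)
    best$coef <- beta[-1L]
  }
  if (any(!is.finite(best$coef)))
    stop("logistic combination failed to converge")
  list(selected_pcs = candidate_pcs[best$sub],
       coefficients = unname(best$coef),
       aic = best$aic, separated = best$separated,
       screened_pcs = candidate_pcs)
}

# Ridge-penalized logistic regression (penalty on slopes only) by Newton
# iteration; keeps coefficients finite under complete separation.
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 200L, tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  P <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X1, y - mu) - P %*% beta
    H <- crossprod(X1 * w, X1) + P
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  if (max(abs(step)) > 1e-6) stop("ridge logistic refit failed to converge")
  drop(beta)
}

#' Assemble a covariance pattern from selected components
#'
#' The pattern voxel weights are the coefficient-weighted sum of the selected
#' voxel components, rescaled to unit norm (the rescaling factor is recorded;
#' it changes raw scores by a constant factor only, which the z-transform
#' absorbs). The derivation control group's raw-score mean and SD are stored
#' so new scans can be z-scored against the derivation controls.
#'
#' @param b an `ssm_pca` object.
#' @param selected_pcs indices of the combined components.
#' @param coefficients logistic slopes aligned with `selected_pcs`.
#' @return A `cov_pattern` with `weights` (unit norm), `mask`,
#'   `selected_pcs`, `coefficients`, `reference_offset`, `norm_factor`, and
#'   `derivation_score_stats` (control mean/SD of raw scores).
#' @export
build_pattern <- function(b, selected_pcs, coefficients) {
  stopifnot(inherits(b, "ssm_pca"))
  if (length(selected_pcs) != length(coefficients))
    stop("coefficients must align with selected_pcs")
  w <- drop(b$voxel_components[, selected_pcs, drop = FALSE] %*% coefficients)
  nf <- sqrt(sum(w^2))
  if (nf < 1e-12) stop("combined pattern vector is zero")
  w <- w / nf
  raw <- drop(b$subject_scores[, selected_pcs, drop = FALSE] %*% coefficients) / nf
  ctrl <- b$group_labels == b$control
  structure(list(weights = w, mask = b$mask, selected_pcs = selected_pcs,
                 coefficients = coefficients, norm_factor = nf,
                 reference_offset = b$reference_offset,
                 derivation_score_stats = list(
                   mean = mean(raw[ctrl]), sd = stats::sd(raw[ctrl])),
                 derivation_scores = raw,
                 derivation_ids = b$subject_ids,
                 derivation_labels = b$group_labels,
                 control = b$control),
            class = "cov_pattern")
}

#' @export
print.cov_pattern <- function(x, ...) {
  cat(sprintf("<cov_pattern> %d voxels, combined PCs {%s}, control raw score %.3g +/- %.3g\n",
              length(x$weights), paste(x$selected_pcs, collapse = ","),
              x$derivation_score_stats$mean, x$derivation_score_stats$sd))
  invisible(x)
}

#' Derive a disease-related covariance pattern from a cohort
#'
#' End-to-end derivation: optional Gaussian smoothing, cohort mask (each scan
#' thresholded at a fraction of its own maximum, masks intersected), log
#' transformation, double centering, subject-space PCA, selection of the
#' leading components covering the variance target, exhaustive AIC-guided
#' logistic combination, and pattern assembly.
#'
#' @param scans list of aligned `pet_volume` objects.
#' @param labels group label per scan.
#' @param control control-group label.
#' @param mask optional precomputed `pet_mask`; built from the scans when
#'   `NULL`.
#' @param mask_fraction threshold fraction for the cohort mask.
#' @param fwhm_mm if not `NULL`, smooth every scan with this kernel first.
#' @param variance_target cumulative variance fraction for component
#'   selection.
#' @param max_subset_size largest logistic subset searched.
#' @param exact_size,screen_p see [fit_logistic_combination()].
#' @return An `ssm_derivation` list: `pattern` (a `cov_pattern`), `basis`
#'   (the `ssm_pca`), `profiles` (residual `ssm_profiles`), `candidate_pcs`,
#'   and `fit` (the logistic search result).
#' @export
derive_pattern <- function(scans, labels, control = "HC", mask = NULL,
                           mask_fraction = 0.35, fwhm_mm = NULL,
                           variance_target = 0.5, max_subset_size = 4L,
                           exact_size = NULL, screen_p = 0.05) {
  if (!is.null(fwhm_mm)) scans <- lapply(scans, gaussian_smooth, fwhm_mm = fwhm_mm)
  if (is.null(mask)) mask <- cohort_mask(scans, fraction = mask_fraction)
  prof <- build_profiles(scans, mask, labels, control = control)
  derive_from_profiles(prof, variance_target = variance_target,
                       max_subset_size = max_subset_size,
                       exact_size = exact_size, screen_p = screen_p)
}

# Shared derivation path from log profiles; also the per-iteration route of
# the bootstrap, so point estimate and resamples run identical code.
derive_from_profiles <- function(prof, variance_target = 0.5,
                                 max_subset_size = 4L, exact_size = NULL,
                                 screen_p = 0.05) {
  res <- double_center(prof)
  basis <- run_pca(res)
  cand <- select_components(basis, variance_target = variance_target)
  fit <- fit_logistic_combination(basis, cand,
                                  max_subset_size = max_subset_size,
                                  exact_size = exact_size,
                                  screen_p = screen_p)
  pattern <- build_pattern(basis, fit$selected_pcs, fit$coefficients)
  structure(list(pattern = pattern, basis = basis, profiles = res,
                 candidate_pcs = cand, fit = fit),
            class = "ssm_derivation")
}

#' @export
print.ssm_derivation <- function(x, ...) {
  cat(sprintf("<ssm_derivation> %d subjects; %d candidate PCs (%.1f%% variance); combined {%s}\n",
              nrow(x$basis$subject_scores), length(x$candidate_pcs),
              100 * sum(x$basis$variance_fractions[x$candidate_pcs]),
              paste(x$fit$selected_pcs, collapse = ",")))
  print(x$pattern)
  invisible(x)
}

#' Correlate a derived pattern with a ground-truth component
#'
#' Convenience check for simulation studies: vectorizes a ground-truth
#' component array over the pattern's analysis mask and returns its Pearson
#' correlation with the pattern weights.
#'
#' @param pattern a `cov_pattern`.
#' @param truth the `truth` element of [simulate_cohort()].
#' @param component which ground-truth component to compare against.
#' @return The correlation (sign retained; magnitude is the recovery measure).
#' @export
recovery_correlation <- function(pattern, truth, component = 1L) {
  arr <- truth$component_arrays[[component]]
  gt <- arr[pattern$mask$voxel_order]
  if (stats::sd(gt) == 0) stop("ground-truth component has no support on the mask")
  stats::cor(pattern$weights, gt)
}
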