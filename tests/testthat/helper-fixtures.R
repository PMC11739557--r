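# Shared fixture builders: everything is generated in code at test time.

# small random positive volume
rand_volume <- function(dims = c(6, 6, 6), seed = 1, voxel_size = c(2, 2, 2),
                        lo = 0.5, hi = 2) {
  set.seed(seed)
  new_volume(array(stats::runif(prod(dims), lo, hi), dim = dims),
             voxel_size = voxel_size)
}

# reduced-size synthetic cohort for fast end-to-end tests (16^3 grid, 8+8)
tiny_cfg <- function(seed = 1, effect_size = 3, noise_sd = 0.05,
                     loading_sd = 1, n_validation = 0) {
  sim_config(grid_shape = c(16, 16, 16), n_controls = 8, n_patients = 8,
             n_validation = n_validation, effect_size = effect_size,
             noise_sd = noise_sd, loading_sd = loading_sd, seed = seed)
}

tiny_cohort <- function(seed = 1, ...) simulate_cohort(tiny_cfg(seed = seed, ...))

# hand-built pattern on an arbitrary mask, for scoring/comparison tests
manual_pattern <- function(weights, mask, reference_offset = NULL,
                           control = "HC", score_mean = 0, score_sd = 1) {
  structure(list(weights = weights, mask = mask,
                 selected_pcs = 1L, coefficients = 1,
                 norm_factor = 1,
                 reference_offset = reference_offset %||% rep(0, mask$n_voxels),
                 derivation_score_stats = list(mean = score_mean, sd = score_sd),
                 control = control),
            class = "cov_pattern")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# profile matrix object built directly from a numeric matrix
manual_profiles <- function(values, labels, control = "HC", state = "log") {
  mask <- new_mask(array(TRUE, dim = c(ncol(values), 1, 1)))
  ssmpca:::new_profiles(values, state = state,
                        subject_ids = paste0("s", seq_len(nrow(values))),
                        group_labels = labels, mask = mask, control = control)
}

# ssm_pca object with prescribed subject scores (for logistic-selection tests)
manual_basis <- function(subject_scores, labels, control = "HC") {
  k <- ncol(subject_scores)
  set.seed(99)
  V <- qr.Q(qr(matrix(stats::rnorm(50 * k), 50, k)))
  mask <- new_mask(array(TRUE, dim = c(50, 1, 1)))
  structure(list(voxel_components = V, subject_scores = subject_scores,
                 variance_fractions = rep(1 / k, k),
                 subject_ids = paste0("s", seq_len(nrow(subject_scores))),
                 group_labels = labels, control = control, mask = mask,
                 reference_offset = rep(0, 50)),
            class = "ssm_pca")
}
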