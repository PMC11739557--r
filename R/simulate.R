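#' Simulation configuration for synthetic PET cohorts
#'
#' Defines the generative model for a synthetic cohort of spatially normalized
#' FDG-PET-like volumes carrying a known covariance structure:
#' \deqn{scan_s = g_s \exp(T + \sum_k a_{sk} \phi_k + \epsilon_s)}
#' with template log-intensity \eqn{T}, orthonormal smooth spatial components
#' \eqn{\phi_k}, per-subject loadings \eqn{a_{sk}}, a multiplicative global
#' scale \eqn{g_s} (the nuisance the scaled-subprofile log/centering step
#' removes exactly), and smooth additive log-space noise \eqn{\epsilon_s}.
#' Patients' component-1 loadings are shifted upward by
#' `effect_size * loading_sd`; clinical covariates are linearly coupled (with
#' noise) to the component-1 loading, with a negative tremor-score slope
#' emulating the inverse severity correlation seen in disease cohorts.
#'
#' Defaults mirror the reference study design: 18 controls and 16 patients in
#' the derivation sample plus 8 patients in an independent validation sample,
#' on a 32^3 grid of 2 mm voxels, with 3 latent components.
#'
#' @param grid_shape integer length-3 grid dimensions (each >= 16).
#' @param voxel_size_mm voxel edge lengths, mm.
#' @param n_controls,n_patients derivation group sizes (each >= 2).
#' @param n_validation patients in the prospective validation cohort (>= 0).
#' @param n_components number of latent spatial components K.
#' @param effect_size group mean shift of the component-1 loading, in units of
#'   `loading_sd`.
#' @param loading_sd SD of the per-subject component loadings.
#' @param noise_sd SD of the smooth voxel noise, log-intensity units.
#' @param global_scale_range interval for the per-subject multiplicative
#'   global factor.
#' @param covariate_coupling list with `tremor_intercept`, `tremor_slope`
#'   (negative by default), `tremor_noise_sd`, and the analogous `stroop_*`
#'   entries, linking simulated clinical scores to the component-1 loading.
#' @param seed integer random seed; identical seeds give bit-identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(32, 32, 32),
                       voxel_size_mm = c(2, 2, 2),
                       n_controls = 18,
                       n_patients = 16,
                       n_validation = 8,
                       n_components = 3,
                       effect_size = 3,
                       loading_sd = 1,
                       noise_sd = 0.05,
                       global_scale_range = c(0.8, 1.2),
                       covariate_coupling = list(
                         tremor_intercept = 30, tremor_slope = -8,
                         tremor_noise_sd = 14,
                         stroop_intercept = 80, stroop_slope = 6,
                         stroop_noise_sd = 10.5),
                       seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              n_validation = as.integer(n_validation),
              n_components = as.integer(n_components),
              effect_size = as.numeric(effect_size),
              loading_sd = as.numeric(loading_sd),
              noise_sd = as.numeric(noise_sd),
              global_scale_range = as.numeric(global_scale_range),
              covariate_coupling = covariate_coupling,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L) stop("grid_shape must have 3 dimensions")
  if (cfg$n_controls < 2L || cfg$n_patients < 2L)
    stop("derivation needs at least 2 subjects per group")
  if (cfg$n_validation < 0L) stop("n_validation must be >= 0")
  if (cfg$n_components < 1L) stop("need at least one latent component")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$loading_sd < 0 || cfg$noise_sd < 0) stop("scales must be >= 0")
  if (length(cfg$global_scale_range) != 2L ||
      any(cfg$global_scale_range <= 0) ||
      diff(cfg$global_scale_range) < 0)
    stop("global_scale_range must be a positive non-decreasing interval")
  invisible(cfg)
}

#' Synthetic brain template (log intensity)
#'
#' An ellipsoidal "brain" with a high-intensity outer shell emulating cortical
#' gray matter (intensities above 35% of the volume maximum, so the standard
#' threshold mask retains it), a lower-intensity interior, a faint positive
#' background, and smooth seeded interior variation. Returned in log-intensity
#' units; `exp()` of the data gives the intensity template.
#'
#' @param cfg a [sim_config()].
#' @return A `pet_volume` of log intensities, with attributes `support` (the
#'   logical gray-matter shell array) and `brain` (shell plus interior).
#' @export
make_template <- function(cfg) {
  validate_sim_config(cfg)
  d <- cfg$grid_shape
  if (any(d < 16L)) stop("grid too small to contain the ellipsoid (need >= 16 per axis)")
  centre <- (d + 1) / 2
  semi <- 0.42 * d
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  rho <- sqrt(((ix - centre[1]) / semi[1])^2 +
              ((iy - centre[2]) / semi[2])^2 +
              ((iz - centre[3]) / semi[3])^2)
  shell <- rho <= 1 & rho >= 0.72
  interior <- rho < 0.72
  tmpl <- array(log(1.5), dim = d)          # faint positive background
  tmpl[interior] <- log(28)                 # white-matter analogue, below mask
  tmpl[shell] <- log(100)                   # gray-matter analogue shell
  # smooth seeded variation inside the brain, small enough not to cross the
  # 35%-of-max threshold on either side
  noise <- with_local_seed(cfg$seed, array(stats::rnorm(prod(d)), dim = d))
  noise <- smooth_array(noise, sigma_vox = c(2, 2, 2))
  brain <- shell | interior
  noise <- noise / stats::sd(noise[brain]) * 0.03
  tmpl[brain] <- tmpl[brain] + noise[brain]
  v <- new_volume(tmpl, voxel_size = cfg$voxel_size_mm,
                  id = "synthetic-template-log")
  attr(v, "support") <- shell
  attr(v, "brain") <- brain
  v
}

# Run code under a private RNG stream; restores the caller's .Random.seed.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a synthetic PET cohort with known ground truth
#'
#' Generates controls ("HC"), derivation patients ("ET1") and validation
#' patients ("ET2") under the generative model documented in [sim_config()].
#' The latent spatial components are built by smoothing white noise on the
#' gray-matter shell and Gram-Schmidt orthonormalizing, so the ground truth is
#' smooth, mutually orthogonal, and exactly reproducible from the seed.
#'
#' @param cfg a [sim_config()].
#' @return A list with `scans` (list of `pet_volume`) and `truth`, the ground
#'   truth holding `template_log`, `support` (shell array), `components`
#'   (voxel-by-K orthonormal matrix on the support, plus `component_arrays`),
#'   `loadings` (subjects-by-K), `global_scales`, `group_labels`, and
#'   `covariates` (data frame of simulated tremor and cognitive scores).
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  tmpl <- make_template(cfg)
  support <- attr(tmpl, "support")
  d <- cfg$grid_shape
  n_total <- cfg$n_controls + cfg$n_patients + cfg$n_validation
  labels <- c(rep("HC", cfg$n_controls), rep("ET1", cfg$n_patients),
              rep("ET2", cfg$n_validation))
  ids <- sprintf("%s_%02d", labels, stats::ave(seq_len(n_total), labels,
                                               FUN = seq_along))
  with_local_seed(cfg$seed + 1L, {
    # latent components: smooth noise on the shell, orthonormalized
    sup_idx <- which(support)
    comp <- matrix(0, length(sup_idx), cfg$n_components)
    comp_arrays <- vector("list", cfg$n_components)
    for (k in seq_len(cfg$n_components)) {
      w <- array(stats::rnorm(prod(d)), dim = d)
      w <- smooth_array(w, sigma_vox = c(2, 2, 2))
      comp[, k] <- w[sup_idx]
    }
    comp <- gram_schmidt(comp)
    for (k in seq_len(cfg$n_components)) {
      arr <- array(0, dim = d)
      arr[sup_idx] <- comp[, k]
      comp_arrays[[k]] <- arr
    }
    # loadings: component 1 shifted in patients by effect_size * loading_sd
    loadings <- matrix(stats::rnorm(n_total * cfg$n_components,
                                    sd = cfg$loading_sd),
                       n_total, cfg$n_components)
    patient <- labels != "HC"
    loadings[patient, 1] <- loadings[patient, 1] +
      cfg$effect_size * cfg$loading_sd
    global_scales <- stats::runif(n_total, cfg$global_scale_range[1],
                                  cfg$global_scale_range[2])
    scans <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      logim <- tmpl$data
      for (k in seq_len(cfg$n_components))
        logim <- logim + loadings[s, k] * comp_arrays[[k]]
      if (cfg$noise_sd > 0) {
        eps <- array(stats::rnorm(prod(d)), dim = d)
        eps <- smooth_array(eps, sigma_vox = c(1.5, 1.5, 1.5))
        eps <- eps / stats::sd(eps[sup_idx]) * cfg$noise_sd
        logim <- logim + eps
      }
      scans[[s]] <- new_volume(global_scales[s] * exp(logim),
                               voxel_size = cfg$voxel_size_mm, id = ids[s])
    }
    cc <- cfg$covariate_coupling
    covariates <- data.frame(
      subject_id = ids, group = labels,
      tremor_score = cc$tremor_intercept + cc$tremor_slope * loadings[, 1] +
        stats::rnorm(n_total, sd = cc$tremor_noise_sd),
      stroop_score = cc$stroop_intercept + cc$stroop_slope * loadings[, 1] +
        stats::rnorm(n_total, sd = cc$stroop_noise_sd),
      stringsAsFactors = FALSE)
    truth <- list(template_log = tmpl, support = support,
                  components = comp, component_arrays = comp_arrays,
                  loadings = loadings, global_scales = global_scales,
                  group_labels = labels, subject_ids = ids,
                  covariates = covariates, config = cfg)
    list(scans = scans, truth = truth)
  })
}

# Orthonormalize the columns of a matrix (classic Gram-Schmidt with
# renormalization; inputs are random smooth fields, never near-collinear).
gram_schmidt <- function(M) {
  for (k in seq_len(ncol(M))) {
    v <- M[, k]
    if (k > 1L) {
      prev <- M[, seq_len(k - 1L), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate component in Gram-Schmidt")
    M[, k] <- v / nv
  }
  M
}

#' Write a simulated cohort to disk
#'
#' Scans and ground-truth components as NIfTI-1, covariates and labels as CSV,
#' configuration as JSON.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$scans)
    write_volume(s, file.path(dir, paste0(s$id, ".nii.gz")))
  tr <- sim$truth
  for (k in seq_along(tr$component_arrays)) {
    img <- RNifti::asNifti(tr$component_arrays[[k]])
    RNifti::pixdim(img) <- tr$config$voxel_size_mm
    RNifti::writeNifti(img, file.path(dir, sprintf("truth_component_%d.nii.gz", k)))
  }
  utils::write.csv(tr$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  cfg <- tr$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
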