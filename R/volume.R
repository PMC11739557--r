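#' Construct a brain volume
#'
#' A `pet_volume` holds one subject's 3-D intensity grid together with its
#' voxel geometry. Volumes entering the SSM/PCA pipeline are assumed to be
#' already spatially normalized to a common space; two volumes are treated as
#' aligned when their grid shapes match and their affines agree within
#' tolerance.
#'
#' @param data 3-D numeric array of non-negative, finite intensities.
#' @param voxel_size numeric length-3, physical voxel edge lengths in mm.
#' @param affine 4x4 grid-to-world transform; defaults to a scaling by
#'   `voxel_size` centred at the origin of the grid.
#' @param id optional subject/scan identifier.
#' @return A `pet_volume` object.
#' @export
new_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL, id = NULL) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), "-D data")
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume contains non-finite intensities")
  if (any(data < 0)) stop("volume contains negative intensities")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  structure(list(data = data, voxel_size = voxel_size, affine = affine, id = id),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume%s> %s grid, voxels %s mm, range [%.4g, %.4g]\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname new_volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "pet_volume")

# Alignment check used throughout: identical shape, affines equal to tol.
volumes_aligned <- function(a_dim, a_aff, b_dim, b_aff, tol = 1e-4) {
  identical(as.integer(a_dim), as.integer(b_dim)) &&
    max(abs(a_aff - b_aff)) <= tol
}

check_aligned <- function(v, m, what = "volume") {
  if (!volumes_aligned(dim(v$data), v$affine, dim(m$data), m$affine))
    stop(what, " is not aligned with the mask (shape/affine mismatch)")
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3-D image.
#' @param id optional identifier; defaults to the file name.
#' @return A [new_volume()] object with geometry taken from the header.
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.array(img)[, , , 1L], dim = d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected 3-D volume in ", path, ", got ", length(d), "-D image")
  }
  vs <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  arr <- as.array(img)
  if (!all(is.finite(arr))) stop("volume ", path, " contains non-finite voxels")
  if (any(arr < 0)) stop("volume ", path, " contains negative voxels")
  new_volume(arr, voxel_size = vs, affine = aff,
             id = if (is.null(id)) basename(path) else id)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks are written as 0/1 integer volumes.
#'
#' @param v a `pet_volume` or `pet_mask`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "pet_mask")) {
    arr <- array(as.integer(v$data), dim = dim(v$data))
    vs <- v$voxel_size
  } else if (is_volume(v)) {
    arr <- v$data
    vs <- v$voxel_size
  } else stop("v must be a pet_volume or pet_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Isotropic Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with the kernel parameterized by its full
#' width at half maximum in millimetres, the convention of PET preprocessing
#' pipelines (the study operating point is 8 mm FWHM). The per-axis standard
#' deviation in voxels is `fwhm_mm / (2 sqrt(2 log 2)) / voxel_size`.
#' Boundaries are handled by half-sample reflection, which preserves the local
#' mean near the brain edge; the kernel is normalized so a constant volume is
#' exactly invariant.
#'
#' @param v a `pet_volume`.
#' @param fwhm_mm positive kernel full width at half maximum, mm.
#' @return The smoothed `pet_volume`.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(is_volume(v))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm <= 0)
    stop("fwhm_mm must be a positive length in mm")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / v$voxel_size
  out <- smooth_array(v$data, sigma_vox)
  out[out < 0] <- 0  # clip convolution round-off below zero
  new_volume(out, voxel_size = v$voxel_size, affine = v$affine, id = v$id)
}

# Separable convolution of a 3-D array with per-axis Gaussian sigmas (voxels),
# half-sample reflect boundary. Each axis pass is a banded-matrix product,
# which keeps the whole operation vectorized.
smooth_array <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    K <- gauss_conv_matrix(d[ax], sigma_vox[ax])
    if (is.null(K)) next  # effectively a delta kernel
    arr <- if (ax == 1L) {
      array(K %*% matrix(arr, d[1]), dim = d)
    } else {
      perm <- c(ax, setdiff(1:3, ax))
      tmp <- aperm(arr, perm)
      tmp <- array(K %*% matrix(tmp, d[ax]), dim = d[perm])
      aperm(tmp, order(perm))
    }
  }
  arr
}

# n x n convolution matrix for a normalized Gaussian with reflect boundary.
# Returns NULL when the kernel is indistinguishable from a delta.
gauss_conv_matrix <- function(n, sigma) {
  if (sigma < 1e-3) return(NULL)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  taps <- (-r):r
  k <- exp(-taps^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- reflect_index(i + taps, n)
    for (t in seq_along(taps)) K[i, j[t]] <- K[i, j[t]] + k[t]
  }
  K
}

# Half-sample symmetric reflection of indices into 1..n (… 2 1 | 1 2 … n | n n-1 …).
reflect_index <- function(idx, n) {
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period  # 0-based, periodized
  idx <- ifelse(idx >= n, period - 1L - idx, idx)
  idx + 1L
}

#' Build a binary analysis mask by intensity thresholding
#'
#' Retains voxels at or above `fraction` of the whole-volume maximum. At the
#' conventional fraction of 0.35 this keeps mainly gray matter in normalized
#' FDG-PET. The mask fixes the voxel vectorization order (ascending linear
#' index in column-major storage) used by all profile matrices and patterns.
#'
#' @param v a `pet_volume`.
#' @param fraction threshold as a fraction of the volume maximum, in (0, 1).
#' @return A `pet_mask`.
#' @export
threshold_mask <- function(v, fraction = 0.35) {
  stopifnot(is_volume(v))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  mx <- max(v$data)
  if (mx <= 0) stop("cannot threshold an all-zero volume (no maximum)")
  new_mask(v$data >= fraction * mx, voxel_size = v$voxel_size, affine = v$affine)
}

#' Construct a binary mask
#'
#' @param data 3-D logical (or 0/1) array.
#' @param voxel_size,affine geometry, as for [new_volume()].
#' @return A `pet_mask` with fields `data`, `n_voxels` and `voxel_order` (the
#'   fixed linear ordering of true voxels).
#' @export
new_mask <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  data <- array(as.logical(data), dim = dim(data))
  if (length(dim(data)) != 3L) stop("mask must be 3-D")
  if (anyNA(data)) stop("mask contains NA")
  voxel_order <- which(data)
  if (length(voxel_order) < 1L) stop("mask is empty (no true voxels)")
  voxel_size <- as.numeric(voxel_size)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  affine <- matrix(as.numeric(affine), 4L, 4L)
  structure(list(data = data, n_voxels = length(voxel_order),
                 voxel_order = voxel_order,
                 voxel_size = voxel_size, affine = affine),
            class = "pet_mask")
}

#' @export
print.pet_mask <- function(x, ...) {
  cat(sprintf("<pet_mask> %s grid, %d voxels in mask (%.1f%%)\n",
              paste(dim(x$data), collapse = "x"), x$n_voxels,
              100 * x$n_voxels / length(x$data)))
  invisible(x)
}

#' Read a 0/1 NIfTI mask
#'
#' @param path path to a NIfTI file holding a 0/1 volume.
#' @return A `pet_mask`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  new_mask(v$data > 0.5, voxel_size = v$voxel_size, affine = v$affine)
}

#' Intersect binary masks
#'
#' A voxel is retained iff it is true in all input masks. Used to build the
#' common analysis mask of a derivation cohort: every subject then has signal
#' in every retained voxel, which the subsequent log transform requires.
#'
#' @param masks a non-empty list of aligned `pet_mask` objects.
#' @return The intersection `pet_mask`.
#' @export
combine_masks <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L) stop("masks must be a non-empty list")
  m1 <- masks[[1L]]
  acc <- m1$data
  for (m in masks[-1L]) {
    if (!volumes_aligned(dim(m1$data), m1$affine, dim(m$data), m$affine))
      stop("masks are not aligned")
    acc <- acc & m$data
  }
  if (!any(acc)) stop("empty intersection: no voxel is inside every mask")
  new_mask(acc, voxel_size = m1$voxel_size, affine = m1$affine)
}

#' Cohort analysis mask
#'
#' Thresholds each scan at `fraction` of its own maximum and intersects the
#' per-scan masks across the cohort.
#'
#' @param scans list of aligned `pet_volume` objects.
#' @param fraction threshold fraction, see [threshold_mask()].
#' @return A `pet_mask`.
#' @export
cohort_mask <- function(scans, fraction = 0.35) {
  combine_masks(lapply(scans, threshold_mask, fraction = fraction))
}

#' Map between 3-D volumes and flat voxel vectors
#'
#' `vectorize()` extracts masked voxels in the mask's fixed voxel order;
#' `devectorize()` inverts it, placing values back on the mask support and
#' zero elsewhere. The two are exact mutual inverses on the mask support.
#'
#' @param v a `pet_volume` aligned with `m`.
#' @param m a `pet_mask`.
#' @param w numeric vector of length `m$n_voxels`.
#' @param clip_negative if `TRUE` (devectorize), negative entries are allowed
#'   and stored as-is in a plain array; the result is a `pet_volume` only when
#'   all values are non-negative, otherwise a bare array with geometry attrs.
#' @return `vectorize`: numeric vector; `devectorize`: `pet_volume` (or array
#'   for signed weight maps).
#' @export
vectorize <- function(v, m) {
  stopifnot(is_volume(v), inherits(m, "pet_mask"))
  check_aligned(v, m)
  as.numeric(v$data[m$voxel_order])
}

#' @rdname vectorize
#' @export
devectorize <- function(w, m, clip_negative = FALSE) {
  stopifnot(inherits(m, "pet_mask"))
  if (length(w) != m$n_voxels)
    stop("length of w (", length(w), ") does not match mask voxel count (",
         m$n_voxels, ")")
  arr <- array(0, dim = dim(m$data))
  arr[m$voxel_order] <- as.numeric(w)
  if (any(arr < 0) && !clip_negative) {
    # signed maps (pattern weights) are legitimate; return a geometry-tagged array
    attr(arr, "voxel_size") <- m$voxel_size
    attr(arr, "affine") <- m$affine
    return(arr)
  }
  new_volume(arr, voxel_size = m$voxel_size, affine = m$affine)
}

#' Write a signed voxel-weight map as NIfTI-1
#'
#' @param w voxel-weight vector on `m`.
#' @param m the `pet_mask` defining the support.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_map <- function(w, m, path) {
  if (length(w) != m$n_voxels) stop("weight length does not match mask")
  arr <- array(0, dim = dim(m$data))
  arr[m$voxel_order] <- as.numeric(w)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- m$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
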