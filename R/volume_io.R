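# Volume containers, NIfTI I/O, denoising, and ROI voxel extraction.

#' PET volume container
#'
#' A light wrapper around a 3D numeric array with voxel spacing and an
#' orientation affine. Intensities are arbitrary SUV-like units; the pipeline
#' never assumes a particular normalization.
#'
#' @param voxels 3D numeric array of finite intensities.
#' @param spacing mm per voxel along each axis (positive triple).
#' @param affine 4x4 voxel-to-world transform; defaults to `diag(spacing)`.
#' @return object of class `pet_volume`.
#' @export
pet_volume <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop_config("volume must be 3D, got %dD", length(dim(voxels)))
  if (!all(is.finite(voxels))) stop_config("volume contains non-finite intensities")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_config("spacing must be three positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  structure(list(voxels = voxels * 1.0, spacing = as.numeric(spacing),
                 affine = affine),
            class = "pet_volume")
}

#' Binary region-of-interest mask
#'
#' @param mask 3D array of 0/1 values.
#' @param min_voxels minimum acceptable ROI size (default 20 voxels).
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(mask, min_voxels = 20L) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop_config("mask must be 3D, got %dD", length(dim(mask)))
  if (!all(mask %in% c(0, 1))) stop_config("mask must be binary (0/1)")
  n <- sum(mask)
  if (n < min_voxels)
    stop_config("ROI has %d voxels, below the minimum of %d", n, min_voxels)
  structure(list(mask = array(as.integer(mask), dim(mask)), n_voxels = as.integer(n)),
            class = "roi_mask")
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [pet_volume()] with spacing and affine taken from the header.
#' @export
read_pet_volume <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_config("expected a 3D image, got %dD (%s)", length(d),
                paste(d, collapse = "x"))
  pd <- abs(RNifti::pixdim(img))
  xf <- RNifti::xform(img)
  pet_volume(array(as.numeric(img), d), spacing = pd[1:3],
             affine = matrix(as.numeric(xf), 4, 4))
}

#' Write a volume as NIfTI-1
#'
#' @param volume a [pet_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_pet_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI ROI mask
#'
#' @inheritParams read_pet_volume
#' @param min_voxels minimum ROI size passed to [roi_mask()].
#' @export
read_roi_mask <- function(path, min_voxels = 20L) {
  vol <- read_pet_volume(path)
  roi_mask(vol$voxels, min_voxels = min_voxels)
}

# 1D convolution along one axis of a 3D array with edge-replicate padding
# (clamped indices). Preserves constants exactly (kernel sums to 1) and the
# total mass of any feature whose kernel support stays inside the grid.
conv_axis_replicate <- function(arr, kernel, axis) {
  n <- dim(arr)[axis]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(arr))
  for (j in seq_along(kernel)) {
    off <- j - 1L - r
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kernel[j] * shifted
  }
  out
}

gaussian_kernel_1d <- function(sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-r, r), sd = sd)
  k / sum(k)
}

#' Denoise a PET volume
#'
#' Separable 3D Gaussian smoothing (default), a cubic median filter, or the
#' identity. Boundaries use edge replication, so constant volumes are exact
#' fixed points of every method.
#'
#' @param volume a [pet_volume()].
#' @param method `"gaussian"`, `"median"`, or `"none"`.
#' @param width Gaussian standard deviation, or median half-width, in voxels.
#' @return a denoised [pet_volume()] with unchanged shape and metadata.
#' @export
denoise_volume <- function(volume, method = c("gaussian", "median", "none"),
                           width = 1) {
  stopifnot(inherits(volume, "pet_volume"))
  method <- match.arg(method)
  if (method == "none") return(volume)
  if (width <= 0) stop_config("width must be > 0 for method '%s'", method)
  v <- volume$voxels
  out <- switch(method,
    gaussian = {
      k <- gaussian_kernel_1d(width)
      conv_axis_replicate(conv_axis_replicate(conv_axis_replicate(v, k, 1L), k, 2L), k, 3L)
    },
    median = {
      w <- as.integer(width)
      offs <- expand.grid(dx = -w:w, dy = -w:w, dz = -w:w)
      d <- dim(v)
      stack <- vapply(seq_len(nrow(offs)), function(i) {
        ix <- pmin(pmax(seq_len(d[1]) + offs$dx[i], 1L), d[1])
        iy <- pmin(pmax(seq_len(d[2]) + offs$dy[i], 1L), d[2])
        iz <- pmin(pmax(seq_len(d[3]) + offs$dz[i], 1L), d[3])
        as.vector(v[ix, iy, iz])
      }, numeric(length(v)))
      array(apply(stack, 1, stats::median), d)
    })
  pet_volume(out, spacing = volume$spacing, affine = volume$affine)
}

#' Extract the ROI voxel sample that feeds clustering
#'
#' Returns the gray value of every voxel inside the mask in a fixed canonical
#' scan order: ascending voxel index with the first axis varying fastest and
#' the third axis slowest (R's native array order). The order is
#' mathematically irrelevant to the clustering but fixes all downstream
#' tie-breaking, making runs exactly reproducible.
#'
#' @param volume a [pet_volume()].
#' @param mask an aligned [roi_mask()].
#' @return a `voxel_sample`: list with `intensities` (length N), `coordinates`
#'   (N x 3 matrix of 0-based voxel indices), and `n`.
#' @export
extract_voxel_sample <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$voxels), dim(mask$mask)))
    stop_config("volume (%s) and mask (%s) shapes differ",
                paste(dim(volume$voxels), collapse = "x"),
                paste(dim(mask$mask), collapse = "x"))
  idx <- which(mask$mask != 0L)
  if (length(idx) == 0L) stop_config("mask is empty")
  structure(
    list(intensities = as.numeric(volume$voxels[idx]),
         coordinates = arrayInd(idx, dim(mask$mask)) - 1L,
         n = length(idx)),
    class = "voxel_sample"
  )
}
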