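# Synthetic PET-like tumor phantoms with planted intensity subregions.
#
# The generator stands in for a patient cohort: each phantom is an ellipsoidal
# "tumor" on a 3D grid whose ROI voxels are drawn from K Gaussian intensity
# components arranged either as concentric shells (core/rim habitats) or as
# random blobs. A binary node label is linked to heterogeneity by scaling the
# gaps between subregion means differently in the two classes.

#' Specification of a single synthetic tumor phantom
#'
#' @param grid_shape integer triple, voxel counts per axis.
#' @param semi_axes ellipsoid semi-axes in voxels; the ellipsoid is centred on
#'   the grid and must fit inside it.
#' @param n_subregions number of planted intensity subregions K.
#' @param subregion_means length-K intensity means (arbitrary SUV-like units).
#' @param subregion_sds length-K intensity standard deviations.
#' @param layout `"nested_shells"` (concentric equal-volume ellipsoidal shells,
#'   subregion 1 innermost) or `"random_blobs"` (Voronoi cells around K random
#'   seed voxels).
#' @param noise_sd standard deviation of additive Gaussian image noise applied
#'   to every voxel, inside and outside the ROI.
#' @param seed integer RNG seed; fixed seed gives bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(20L, 20L, 20L),
                         semi_axes = c(7, 7, 7),
                         n_subregions = 3L,
                         subregion_means = c(2, 4.5, 8),
                         subregion_sds = rep(0.8, 3),
                         layout = c("nested_shells", "random_blobs"),
                         noise_sd = 0.3,
                         seed = 1L) {
  layout <- match.arg(layout)
  grid_shape <- as.integer(grid_shape)
  K <- as.integer(n_subregions)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_config("grid_shape must be three positive integers")
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop_config("semi_axes must be three positive values")
  if (any(semi_axes > (grid_shape - 1) / 2))
    stop_config("ellipsoid with semi-axes (%s) does not fit inside grid (%s)",
                paste(semi_axes, collapse = ","), paste(grid_shape, collapse = ","))
  if (K < 1L) stop_config("n_subregions must be >= 1")
  if (length(subregion_means) != K || length(subregion_sds) != K)
    stop_config("subregion_means and subregion_sds must both have length K = %d", K)
  if (any(subregion_sds < 0)) stop_config("subregion_sds must be >= 0")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(
    list(grid_shape = grid_shape, semi_axes = as.numeric(semi_axes),
         n_subregions = K, subregion_means = as.numeric(subregion_means),
         subregion_sds = as.numeric(subregion_sds), layout = layout,
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Squared normalized ellipsoidal radius of every voxel (1 on the surface).
ellipsoid_radius2 <- function(grid_shape, semi_axes) {
  centre <- (grid_shape + 1) / 2
  ax <- ((seq_len(grid_shape[1]) - centre[1]) / semi_axes[1])^2
  ay <- ((seq_len(grid_shape[2]) - centre[2]) / semi_axes[2])^2
  az <- ((seq_len(grid_shape[3]) - centre[3]) / semi_axes[3])^2
  outer(outer(ax, ay, `+`), az, `+`)
}

#' Generate one synthetic tumor phantom
#'
#' ROI voxels receive intensities drawn from the K Gaussian subregion
#' components arranged per the layout; additive Gaussian noise is then applied
#' to the whole grid. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param node_label optional binary label (0/1) carried on the sample.
#' @return a `phantom_sample`: list with `volume` ([pet_volume()]), `mask`
#'   ([roi_mask()]), `planted_labels` (subregion index per ROI voxel in the
#'   canonical scan order of [extract_voxel_sample()]), and `node_label`.
#' @export
generate_phantom <- function(spec, node_label = NA_integer_) {
  stopifnot(inherits(spec, "phantom_spec"))
  r2 <- ellipsoid_radius2(spec$grid_shape, spec$semi_axes)
  inside <- r2 <= 1
  n_roi <- sum(inside)
  K <- spec$n_subregions
  if (n_roi < K)
    stop_config("ROI has %d voxels, fewer than K = %d subregions", n_roi, K)
  idx <- which(inside) # column-major == canonical (z slowest, x fastest) order

  with_local_seed(spec$seed, {
    lab <- switch(spec$layout,
      nested_shells = {
        # equal-count shells by radius rank: innermost = subregion 1,
        # guaranteed nonempty for K <= n_roi
        r <- r2[idx]
        pmin(ceiling(rank(r, ties.method = "first") * K / n_roi), K)
      },
      random_blobs = {
        coords <- arrayInd(idx, spec$grid_shape)
        seeds <- coords[sample.int(n_roi, K), , drop = FALSE]
        d2 <- sapply(seq_len(K), function(k) {
          rowSums(sweep(coords, 2, seeds[k, ])^2)
        })
        max.col(-d2, ties.method = "first")
      }
    )
    vox <- array(0, spec$grid_shape)
    vox[idx] <- stats::rnorm(n_roi, spec$subregion_means[lab], spec$subregion_sds[lab])
    if (spec$noise_sd > 0) {
      vox <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sd), spec$grid_shape)
    }
    structure(
      list(volume = pet_volume(vox),
           mask = roi_mask(array(as.integer(inside), spec$grid_shape)),
           planted_labels = as.integer(lab),
           node_label = as.integer(node_label),
           spec = spec),
      class = "phantom_sample"
    )
  })
}

#' Specification of a synthetic phantom cohort
#'
#' The node label is linked to heterogeneity through the separation
#' multiplier: per sample, the gaps between consecutive subregion means of the
#' base phantom spec are scaled by `separation_positive` (label 1) or
#' `separation_negative` (label 0). Equal separations yield a null cohort with
#' no class signal.
#'
#' @param n_samples cohort size (>= 4).
#' @param positive_fraction fraction of node-positive samples, in (0, 1);
#'   the positive count is exactly `round(n * positive_fraction)` (half-up).
#' @param separation_positive,separation_negative positive multipliers applied
#'   to the inter-mean gaps for each class.
#' @param phantom base [phantom_spec()] shared by all samples (its seed is
#'   replaced by per-sample seeds derived from `seed`).
#' @param seed cohort-level RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 200L, positive_fraction = 0.5,
                        separation_positive = 3.0, separation_negative = 1.0,
                        phantom = phantom_spec(), seed = 1L) {
  n <- as.integer(n_samples)
  if (n < 4L) stop_config("n_samples must be >= 4 (cannot split smaller cohorts)")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop_config("positive_fraction must lie strictly between 0 and 1")
  if (separation_positive <= 0 || separation_negative <= 0)
    stop_config("separation multipliers must be > 0")
  stopifnot(inherits(phantom, "phantom_spec"))
  structure(
    list(n_samples = n, positive_fraction = positive_fraction,
         separation_positive = separation_positive,
         separation_negative = separation_negative,
         phantom = phantom, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Scale the gaps between consecutive subregion means by `sep`, anchored at the
# first mean: (m1, m1 + s*g1, m1 + s*(g1+g2), ...).
scale_mean_gaps <- function(means, sep) {
  means[1] + sep * cumsum(c(0, diff(means)))
}

#' Generate a synthetic phantom cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of `phantom_sample` objects with `sample_id` names; exactly
#'   `round(n * positive_fraction)` carry `node_label = 1`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  n_pos <- round_half_up(n * spec$positive_fraction)
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  labels <- with_local_seed(derive_seed(spec$seed, "cohort-labels"),
                            sample(labels))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    sep <- if (labels[i] == 1L) spec$separation_positive else spec$separation_negative
    ps <- spec$phantom
    ps$subregion_means <- scale_mean_gaps(ps$subregion_means, sep)
    ps$seed <- derive_seed(spec$seed, i)
    samples[[i]] <- generate_phantom(ps, node_label = labels[i])
    samples[[i]]$sample_id <- sprintf("S%04d", i)
  }
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  samples
}

#' Write a phantom cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' @param cohort list of `phantom_sample`s from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest data frame (sample_id, node_label,
#'   volume_path, mask_path).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    vp <- file.path(dir, paste0(s$sample_id, "_pet.nii.gz"))
    mp <- file.path(dir, paste0(s$sample_id, "_mask.nii.gz"))
    write_pet_volume(s$volume, vp)
    write_pet_volume(pet_volume(s$mask$mask), mp)
    data.frame(sample_id = s$sample_id, node_label = s$node_label,
               volume_path = vp, mask_path = mp, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Patient accounting of the reference study design
#'
#' The clinical study this pipeline emulates screened a radiology database and
#' identified 270 PET/CT patients; 23 were excluded for missing or poor image
#' quality and a further 23 for pre-PET treatment or non-primary ovarian
#' tumors. The function applies those exclusions and returns the resulting
#' cohort size together with the audit trail.
#'
#' @return list with `identified`, `excluded` (named vector), and `included`.
#' @export
reference_cohort_counts <- function() {
  identified <- 270L
  excluded <- c(image_quality = 23L, prior_treatment_or_nonprimary = 23L)
  list(identified = identified, excluded = excluded,
       included = identified - sum(excluded))
}
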