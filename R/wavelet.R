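# 2D discrete wavelet transform feature maps.
#
# The transform is separable: an orthonormal 1D DWT is applied to every image
# row, then to every column of the result, yielding the LL/LH/HL/HH subbands.
# The 1D transform is periodized (odd lengths are first extended by
# replicating the last sample), which keeps the analysis operator exactly
# orthogonal: perfect reconstruction and energy conservation then hold to
# machine precision for any orthonormal filter pair.

wavelet_filters <- function(name) {
  switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop_config("unknown wavelet family '%s' (available: haar, db2)", name)
  )
}

#' DWT and feature-map configuration
#'
#' @param wavelet wavelet family: `"haar"` (default) or `"db2"`.
#' @param level decomposition level (>= 1); levels beyond 1 recurse on LL.
#' @param slice_policy how 2D inputs are taken from the 3D ROI:
#'   `"max_roi_area"` (axial slice with the largest in-mask area; ties to the
#'   lowest index), `"central"` (mask-centroid slice), or `"all_roi_slices"`.
#' @param target_size output feature-map side length in pixels (>= 8).
#' @export
dwt_config <- function(wavelet = "haar", level = 1L,
                       slice_policy = c("max_roi_area", "central", "all_roi_slices"),
                       target_size = 224L) {
  slice_policy <- match.arg(slice_policy)
  wavelet_filters(wavelet) # validates the name
  if (level < 1L) stop_config("level must be >= 1")
  if (target_size < 8L) stop_config("target_size must be >= 8")
  structure(list(wavelet = wavelet, level = as.integer(level),
                 slice_policy = slice_policy, target_size = as.integer(target_size)),
            class = "dwt_config")
}

# Orthogonal periodized analysis matrix for even n: rows 1..n/2 are the
# lowpass filter shifted by 2, rows n/2+1..n the highpass (QMF) filter.
dwt_matrix <- function(n, lo) {
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  W <- matrix(0, n, n)
  half <- n / 2
  for (k in seq_len(half)) {
    pos <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (m in seq_len(L)) {
      W[k, pos[m]] <- W[k, pos[m]] + lo[m]
      W[half + k, pos[m]] <- W[half + k, pos[m]] + hi[m]
    }
  }
  W
}

pad_even <- function(m) {
  if (nrow(m) %% 2 == 1) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (ncol(m) %% 2 == 1) m <- cbind(m, m[, ncol(m), drop = FALSE])
  m
}

dwt2_single <- function(img, lo) {
  img <- pad_even(img)
  nr <- nrow(img); nc <- ncol(img)
  Wc <- dwt_matrix(nc, lo) # acts along rows (across columns)
  Wr <- dwt_matrix(nr, lo) # acts along columns (across rows)
  tmp <- Wr %*% img %*% t(Wc)
  hr <- nr / 2; hc <- nc / 2
  list(ll = tmp[seq_len(hr), seq_len(hc), drop = FALSE],
       lh = tmp[seq_len(hr), hc + seq_len(hc), drop = FALSE],
       hl = tmp[hr + seq_len(hr), seq_len(hc), drop = FALSE],
       hh = tmp[hr + seq_len(hr), hc + seq_len(hc), drop = FALSE])
}

#' 2D discrete wavelet transform of one slice
#'
#' Separable row-then-column 1D DWT with orthonormal filters. The LL subband
#' is the coarse approximation; LH/HL/HH carry horizontal/vertical/diagonal
#' detail. With `level > 1` the decomposition recurses on LL and the detail
#' subbands of the final level are returned.
#'
#' @param slice_image 2D numeric matrix, both dimensions >= 2.
#' @param config a [dwt_config()].
#' @return a `subband_set`: list `ll`, `lh`, `hl`, `hh` (equal-shaped
#'   matrices), plus `input_dim` and `config` for inversion.
#' @export
dwt2 <- function(slice_image, config = dwt_config()) {
  stopifnot(inherits(config, "dwt_config"))
  img <- as.matrix(slice_image)
  if (any(dim(img) < 2L))
    stop_config("slice must be at least 2x2, got %s", paste(dim(img), collapse = "x"))
  lo <- wavelet_filters(config$wavelet)
  dims <- list(dim(img))
  sb <- dwt2_single(img, lo)
  lev <- 1L
  while (lev < config$level && all(dim(sb$ll) >= 2L)) {
    dims <- c(dims, list(dim(sb$ll)))
    sb <- c(dwt2_single(sb$ll, lo), list(deeper = sb[c("lh", "hl", "hh")]))
    lev <- lev + 1L
  }
  structure(c(sb[c("ll", "lh", "hl", "hh")],
              list(input_dim = dims, config = config)),
            class = "subband_set")
}

#' Inverse 2D discrete wavelet transform (level 1)
#'
#' Exact inverse of [dwt2()] at `level = 1`: reconstructs the input slice to
#' machine precision (the analysis operator is orthogonal, so the inverse is
#' its transpose, followed by removal of any odd-length padding).
#'
#' @param subbands a `subband_set` from [dwt2()] with `level = 1`.
#' @return the reconstructed 2D matrix with the original input dimensions.
#' @export
idwt2 <- function(subbands) {
  stopifnot(inherits(subbands, "subband_set"))
  if (subbands$config$level != 1L)
    stop_config("idwt2 supports level-1 subband sets")
  lo <- wavelet_filters(subbands$config$wavelet)
  tmp <- rbind(cbind(subbands$ll, subbands$lh), cbind(subbands$hl, subbands$hh))
  nr <- nrow(tmp); nc <- ncol(tmp)
  rec <- t(dwt_matrix(nr, lo)) %*% tmp %*% dwt_matrix(nc, lo)
  d <- subbands$input_dim[[1]]
  rec[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

#' Select 2D slices from a masked volume
#'
#' Axial slices (third array axis) are extracted with out-of-mask pixels
#' zeroed.
#'
#' @param volume a [pet_volume()].
#' @param mask an aligned [roi_mask()].
#' @param policy `"max_roi_area"` (largest in-mask area, ties to the lowest
#'   slice index), `"central"` (slice nearest the mask centroid), or
#'   `"all_roi_slices"` (every slice intersecting the mask).
#' @return list of 2D matrices; each carries its slice index as attribute
#'   `"slice"`.
#' @export
select_slice <- function(volume, mask,
                         policy = c("max_roi_area", "central", "all_roi_slices")) {
  policy <- match.arg(policy)
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$voxels), dim(mask$mask)))
    stop_config("volume and mask shapes differ")
  areas <- apply(mask$mask, 3, sum)
  if (sum(areas) == 0) stop_config("mask is empty")
  zs <- switch(policy,
    max_roi_area = which.max(areas), # which.max takes the first (lowest) maximum
    central = {
      zc <- sum(seq_along(areas) * areas) / sum(areas)
      round_half_up(zc)
    },
    all_roi_slices = which(areas > 0)
  )
  lapply(zs, function(z) {
    sl <- volume$voxels[, , z] * (mask$mask[, , z] != 0)
    attr(sl, "slice") <- z
    sl
  })
}

# Bilinear resize via EBImage; identity shortcut when already at target size.
resize_bilinear <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  out <- EBImage::resize(m, w = size, h = size, filter = "bilinear")
  matrix(as.numeric(out), size, size)
}

minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

#' Assemble the 3-channel CNN feature map from DWT subbands
#'
#' The LL, LH and HL subbands (HH is computed but deliberately excluded) are
#' each min-max normalized to \[0, 1\] independently (a constant subband maps
#' to all zeros), bilinearly resized to `target_size` x `target_size`, and
#' stacked in the fixed channel order (LL, LH, HL).
#'
#' @param subbands a `subband_set` from [dwt2()].
#' @param config a [dwt_config()] providing `target_size`.
#' @return a `feature_map`: list with `channels`
#'   (`target_size x target_size x 3` array, all values in \[0, 1\]) and
#'   `normalization_record` (per-channel input min/max).
#' @export
assemble_feature_map <- function(subbands, config = dwt_config()) {
  stopifnot(inherits(subbands, "subband_set"), inherits(config, "dwt_config"))
  chans <- list(LL = subbands$ll, LH = subbands$lh, HL = subbands$hl)
  rec <- lapply(chans, range)
  arr <- array(0, c(config$target_size, config$target_size, 3L),
               dimnames = list(NULL, NULL, names(chans)))
  for (i in seq_along(chans)) {
    arr[, , i] <- pmin(pmax(resize_bilinear(minmax01(chans[[i]]), config$target_size), 0), 1)
  }
  structure(list(channels = arr, normalization_record = rec, config = config),
            class = "feature_map")
}

#' One-call feature map for a sample: slice selection, DWT, assembly
#'
#' @param volume,mask as in [select_slice()].
#' @param config a [dwt_config()]; its `slice_policy` picks the slice (for
#'   `"all_roi_slices"` only the first is used here).
#' @return a `feature_map`.
#' @export
feature_map_from_sample <- function(volume, mask, config = dwt_config()) {
  sl <- select_slice(volume, mask, config$slice_policy)[[1]]
  assemble_feature_map(dwt2(sl, config), config)
}
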