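# Gaussian-mixture subregion segmentation of ROI voxels by gray value.
#
# Clustering is 1D by design: each ROI voxel is characterised by its intensity
# alone, and spatial coordinates are never used as features. The EM fit is
# restarted from several k-means++-style seedings and the restart with the
# best final log-likelihood wins; components are relabelled by ascending mean
# so that the labeling is invariant to the internal component order.

#' Gaussian mixture segmentation configuration
#'
#' @param K number of mixture components / subregions (default 3).
#' @param covariance_model `"diagonal"` (per-component variance; in 1D this is
#'   a scalar per component) or `"spherical"` (single shared variance).
#' @param n_restarts independent EM restarts; the best final log-likelihood
#'   is kept.
#' @param max_iter EM iteration cap per restart.
#' @param tol convergence threshold on the change in mean log-likelihood.
#' @param seed RNG seed controlling all restarts.
#' @export
gmm_config <- function(K = 3L, covariance_model = c("diagonal", "spherical"),
                       n_restarts = 5L, max_iter = 200L, tol = 1e-4,
                       seed = 1L) {
  covariance_model <- match.arg(covariance_model)
  K <- as.integer(K)
  if (K < 1L) stop_config("K must be >= 1")
  if (n_restarts < 1L) stop_config("n_restarts must be >= 1")
  if (tol <= 0) stop_config("tol must be > 0")
  structure(list(K = K, covariance_model = covariance_model,
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "gmm_config")
}

# k-means++ seeding of component means on 1D data.
kmeanspp_means <- function(x, K) {
  means <- numeric(K)
  means[1] <- x[sample.int(length(x), 1L)]
  if (K > 1L) {
    d2 <- (x - means[1])^2
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / length(x), length(x))
      means[k] <- x[sample.int(length(x), 1L, prob = p)]
      d2 <- pmin(d2, (x - means[k])^2)
    }
  }
  means
}

# One EM run; returns means/sds/weights/responsibilities/loglik.
gmm_em_once <- function(x, K, covariance_model, max_iter, tol) {
  n <- length(x)
  var_floor <- max(stats::var(x), .Machine$double.eps) * 1e-6 + 1e-12
  mu <- kmeanspp_means(x, K)
  sg <- rep(max(stats::sd(x) / K, sqrt(var_floor)), K)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k) {
      stats::dnorm(x, mu[k], sg[k], log = TRUE) + log(w[k])
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    ll <- mean(lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * max(1, abs(ll))) break
    ll_old <- ll
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- colSums(resp * outer(x, mu, `-`)^2) / nk
    if (covariance_model == "spherical") v[] <- sum(v * nk) / n
    sg <- sqrt(pmax(v, var_floor))
  }
  list(means = mu, sds = sg, weights = w, resp = resp, loglik = ll * n)
}

#' Fit a Gaussian mixture segmentation of ROI voxels
#'
#' Each voxel is assigned to the component of maximum posterior
#' responsibility. The fit is deterministic for a fixed config seed; the best
#' of `n_restarts` runs (by final log-likelihood) is selected, and components
#' are relabelled in ascending order of mean intensity.
#'
#' If a component captures no voxels at assignment time, the voxel with the
#' lowest maximum responsibility is reassigned to it (with a warning) so that
#' every cluster is nonempty, as the validity indices require.
#'
#' @param sample a `voxel_sample` from [extract_voxel_sample()].
#' @param config a [gmm_config()].
#' @return a `subregion_labeling`: list with `labels` (1..K per voxel in scan
#'   order), `K`, `cluster_sizes`, `loglik`, `restart_logliks`, `means`,
#'   `sds`, `weights`, and the `config` used.
#' @export
fit_gmm_segmentation <- function(sample, config = gmm_config()) {
  stopifnot(inherits(sample, "voxel_sample"), inherits(config, "gmm_config"))
  x <- sample$intensities
  K <- config$K
  if (!all(is.finite(x))) stop_config("sample contains non-finite intensities")
  if (length(x) < K)
    stop_config("N = %d voxels is insufficient for K = %d components", length(x), K)

  if (K == 1L) {
    labels <- rep(1L, length(x))
    ll <- sum(stats::dnorm(x, mean(x), max(stats::sd(x), 1e-12), log = TRUE))
    return(new_labeling(labels, K, ll, ll, mean(x), stats::sd(x), 1, config))
  }

  fits <- with_local_seed(config$seed, {
    lapply(seq_len(config$n_restarts), function(r) {
      gmm_em_once(x, K, config$covariance_model, config$max_iter, config$tol)
    })
  })
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(lls)]]

  ord <- order(best$means)
  resp <- best$resp[, ord, drop = FALSE]
  labels <- max.col(resp, ties.method = "first")

  # empty-cluster repair
  for (k in seq_len(K)) {
    if (!any(labels == k)) {
      cand <- which.min(apply(resp, 1, max))
      warning(sprintf("component %d captured no voxels; reassigning voxel %d", k, cand))
      labels[cand] <- k
    }
  }
  new_labeling(as.integer(labels), K, max(lls), lls,
               best$means[ord], best$sds[ord], best$weights[ord], config)
}

new_labeling <- function(labels, K, loglik, restart_logliks, means, sds, weights, config) {
  structure(
    list(labels = as.integer(labels), K = as.integer(K),
         cluster_sizes = tabulate(labels, nbins = K),
         loglik = loglik, restart_logliks = restart_logliks,
         means = means, sds = sds, weights = weights, config = config),
    class = "subregion_labeling"
  )
}

#' Paint a subregion labeling back into a 3D label grid
#'
#' Background voxels are 0; ROI voxels carry their subregion index 1..K, using
#' the same canonical scan order as [extract_voxel_sample()], so
#' volume -> sample -> labeling -> volume round-trips exactly.
#'
#' @param labeling a `subregion_labeling`.
#' @param mask the [roi_mask()] the sample was extracted from.
#' @return 3D integer array of labels.
#' @export
labeling_to_volume <- function(labeling, mask) {
  stopifnot(inherits(labeling, "subregion_labeling"), inherits(mask, "roi_mask"))
  idx <- which(mask$mask != 0L)
  if (length(idx) != length(labeling$labels))
    stop_config("labeling length (%d) does not match mask voxel count (%d)",
                length(labeling$labels), length(idx))
  out <- array(0L, dim(mask$mask))
  out[idx] <- labeling$labels
  out
}
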