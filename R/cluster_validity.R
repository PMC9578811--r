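# Cluster-validity heterogeneity features: Calinski-Harabasz, mean
# silhouette, and Davies-Bouldin.
#
# These three indices score how well-separated the fitted intensity
# subregions are and serve as the tabular heterogeneity features of the
# pipeline. All distances are Euclidean (absolute differences in 1D). The
# Davies-Bouldin implementation follows the mean-pairwise-distance definition
# of cluster closeness, avg(C) = 2/(|C|(|C|-1)) * sum_{i<j} dist(x_i, x_j),
# which differs numerically from the more common mean-distance-to-centroid
# variant; the latter is available behind a `variant` flag but the pipeline
# default is the pairwise form.

validity_inputs <- function(sample, labeling) {
  x <- if (inherits(sample, "voxel_sample")) sample$intensities else as.numeric(sample)
  lab <- if (inherits(labeling, "subregion_labeling")) labeling$labels else as.integer(labeling)
  if (length(x) != length(lab))
    stop_config("sample (%d) and labeling (%d) lengths differ", length(x), length(lab))
  K <- max(lab)
  if (any(lab < 1L)) stop_config("labels must be in 1..K")
  sizes <- tabulate(lab, nbins = K)
  if (any(sizes == 0L)) stop_config("every cluster in 1..%d must be nonempty", K)
  list(x = x, lab = lab, K = K, N = length(x), sizes = sizes)
}

#' Calinski-Harabasz index (CHI)
#'
#' Ratio of between-cluster to within-cluster dispersion:
#' \deqn{CH = \frac{\sum_k n_k \|c_k - c\|^2 / (K-1)}
#'            {\sum_k \sum_{i \in C_k} (x_i - c_k)^2 / (N-K)}}
#' with \eqn{c_k} the cluster means and \eqn{c} the global mean. Higher values
#' indicate better-separated subregions.
#'
#' @param sample a `voxel_sample` or numeric vector of intensities.
#' @param labeling a `subregion_labeling` or integer vector of labels in 1..K.
#' @return nonnegative scalar; `Inf` (with a warning) when the within-cluster
#'   dispersion is exactly zero.
#' @export
calinski_harabasz <- function(sample, labeling) {
  v <- validity_inputs(sample, labeling)
  if (v$K < 2L) stop_config("CHI is undefined for K < 2")
  if (v$N <= v$K) stop_config("CHI is degenerate for N <= K")
  centers <- vapply(seq_len(v$K), function(k) mean(v$x[v$lab == k]), 0)
  global <- mean(v$x)
  between <- sum(v$sizes * (centers - global)^2) / (v$K - 1)
  within <- sum((v$x - centers[v$lab])^2) / (v$N - v$K)
  if (within == 0) {
    warning("zero within-cluster dispersion; CHI is infinite")
    return(Inf)
  }
  between / within
}

#' Mean silhouette coefficient
#'
#' Per point, cohesion \eqn{a_i} is the mean distance to the other members of
#' its own cluster and separation \eqn{b_i} is the smallest over other
#' clusters of the mean distance to that cluster's members;
#' \eqn{s_i = (b_i - a_i)/\max(a_i, b_i)}. The index is the mean of
#' \eqn{s_i} over all points and lies in \eqn{[-1, 1]}. Members of singleton
#' clusters contribute \eqn{s_i = 0}, the usual convention.
#'
#' @inheritParams calinski_harabasz
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_mean <- function(sample, labeling) {
  v <- validity_inputs(sample, labeling)
  if (v$K < 2L) stop_config("silhouette is undefined for K < 2")
  D <- abs(outer(v$x, v$x, `-`))
  cl_sum <- vapply(seq_len(v$K), function(k) {
    rowSums(D[, v$lab == k, drop = FALSE])
  }, numeric(v$N)) # N x K: summed distance from each point to each cluster
  sizes <- v$sizes
  own <- v$lab
  a <- (cl_sum[cbind(seq_len(v$N), own)]) / pmax(sizes[own] - 1L, 1L)
  mean_to <- sweep(cl_sum, 2, sizes, `/`)
  mean_to[cbind(seq_len(v$N), own)] <- Inf
  b <- apply(mean_to, 1, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[sizes[own] == 1L] <- 0
  mean(s)
}

#' Davies-Bouldin index (DBI)
#'
#' \deqn{DB = \frac{1}{K} \sum_i \max_{j \ne i}
#'       \frac{avg(C_i) + avg(C_j)}{d_{cen}(C_i, C_j)}}
#' where by default \eqn{avg(C)} is the mean pairwise distance between members
#' of the cluster and \eqn{d_{cen}} the distance between cluster centers.
#' Lower is better. `variant = "centroid"` switches \eqn{avg(C)} to the mean
#' distance to the cluster centroid for comparison with common library
#' implementations; on well-formed 1D clusters the two variants differ (the
#' pairwise form is roughly twice the centroid form).
#'
#' @inheritParams calinski_harabasz
#' @param variant `"pairwise"` (default) or `"centroid"`.
#' @return nonnegative scalar; `Inf` (with a warning) when two cluster
#'   centers coincide.
#' @export
davies_bouldin <- function(sample, labeling, variant = c("pairwise", "centroid")) {
  variant <- match.arg(variant)
  v <- validity_inputs(sample, labeling)
  if (v$K < 2L) stop_config("DBI is undefined for K < 2")
  if (variant == "pairwise" && any(v$sizes < 2L))
    stop_config("pairwise DBI requires every cluster to have >= 2 members")
  centers <- vapply(seq_len(v$K), function(k) mean(v$x[v$lab == k]), 0)
  avg <- vapply(seq_len(v$K), function(k) {
    xs <- v$x[v$lab == k]
    if (variant == "pairwise") {
      n <- length(xs)
      sum(abs(outer(xs, xs, `-`))) / (n * (n - 1))
    } else {
      mean(abs(xs - centers[k]))
    }
  }, 0)
  dcen <- abs(outer(centers, centers, `-`))
  if (any(dcen[upper.tri(dcen)] == 0)) {
    warning("coincident cluster centers; DBI is infinite")
    return(Inf)
  }
  R <- outer(avg, avg, `+`) / dcen
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Bundle the three validity indices as heterogeneity features
#'
#' @inheritParams davies_bouldin
#' @return a `cluster_features` list: `chi`, `silhouette`, `dbi`, plus the
#'   provenance fields `K`, `N`.
#' @export
compute_cluster_features <- function(sample, labeling, variant = "pairwise") {
  v <- validity_inputs(sample, labeling)
  structure(
    list(chi = calinski_harabasz(sample, labeling),
         silhouette = silhouette_mean(sample, labeling),
         dbi = davies_bouldin(sample, labeling, variant = variant),
         K = v$K, N = v$N),
    class = "cluster_features"
  )
}

#' Per-sample validity features for a whole cohort
#'
#' Runs denoise -> ROI extraction -> GMM segmentation -> validity indices on
#' every sample and tabulates the results.
#'
#' @param cohort list of `phantom_sample`s (or lists with `volume`, `mask`,
#'   `node_label`, `sample_id`).
#' @param gmm a [gmm_config()]; a distinct sub-seed is derived per sample.
#' @param denoise_method,denoise_width passed to [denoise_volume()].
#' @return data.frame: sample_id, chi, silhouette, dbi, K, N, node_label.
#' @export
cohort_cluster_features <- function(cohort, gmm = gmm_config(),
                                    denoise_method = "gaussian",
                                    denoise_width = 1) {
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    vol <- denoise_volume(s$volume, method = denoise_method, width = denoise_width)
    vs <- extract_voxel_sample(vol, s$mask)
    cfg <- gmm
    cfg$seed <- derive_seed(gmm$seed, i)
    feats <- compute_cluster_features(vs, fit_gmm_segmentation(vs, cfg))
    data.frame(sample_id = if (!is.null(s$sample_id)) s$sample_id else sprintf("S%04d", i),
               chi = feats$chi, silhouette = feats$silhouette, dbi = feats$dbi,
               K = feats$K, N = feats$N,
               node_label = if (!is.null(s$node_label)) s$node_label else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
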