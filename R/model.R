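# Dataset splitting, correlation-based feature screening, and SVM fusion of
# the CNN embedding with the cluster-validity features.
#
# Everything fitted here — screening correlations, standardisation
# parameters, the SVM itself — uses the training partition only; the test
# partition enters exclusively at prediction time.

#' Split a labeled cohort into training and test partitions
#'
#' Training size is exactly `round(train_fraction * n)` (half rounded up).
#' Under stratification, per-class training counts are allocated by largest
#' remainder so class proportions are preserved to within one sample while
#' the total is met exactly.
#'
#' @param ids character or integer sample identifiers.
#' @param labels binary labels aligned with `ids` (required when
#'   `stratified = TRUE`).
#' @param train_fraction fraction of samples assigned to training.
#' @param seed RNG seed; a fixed seed gives a fixed split.
#' @param stratified preserve class proportions (default `TRUE`).
#' @param allow_empty_test permit `train_fraction = 1`; otherwise a fraction
#'   that empties either partition is an error.
#' @return a `split_assignment`: list with `train_ids`, `test_ids` and the
#'   settings used.
#' @export
split_dataset <- function(ids, labels = NULL, train_fraction = 0.7, seed = 1L,
                          stratified = TRUE, allow_empty_test = FALSE) {
  n <- length(ids)
  if (n < 4L) stop_config("need at least 4 samples to split")
  if (anyDuplicated(ids)) stop_config("ids must be unique")
  n_train <- round_half_up(train_fraction * n)
  if ((n_train >= n || n_train < 1L) && !allow_empty_test)
    stop_config("train_fraction %.2f empties a partition (set allow_empty_test)", train_fraction)
  n_train <- min(max(n_train, 0L), n)

  if (stratified) {
    if (is.null(labels)) stop_config("stratified split requires labels")
    if (length(unique(labels)) < 2L && !allow_empty_test)
      stop_config("stratification requires both classes to be present")
    classes <- sort(unique(labels))
    target <- train_fraction * table(factor(labels, levels = classes))
    alloc <- floor(target)
    short <- n_train - sum(alloc)
    if (short > 0) {
      ord <- order(target - alloc, decreasing = TRUE)
      alloc[ord[seq_len(short)]] <- alloc[ord[seq_len(short)]] + 1
    } else if (short < 0) {
      ord <- order(target - alloc)
      alloc[ord[seq_len(-short)]] <- alloc[ord[seq_len(-short)]] - 1
    }
    train_ids <- with_local_seed(seed, {
      unlist(lapply(seq_along(classes), function(ci) {
        ic <- which(labels == classes[ci])
        ic[sample.int(length(ic), alloc[ci])]
      }))
    })
  } else {
    train_ids <- with_local_seed(seed, sample.int(n, n_train))
  }
  train_ids <- sort(train_ids)
  structure(list(train_ids = ids[train_ids], test_ids = ids[setdiff(seq_len(n), train_ids)],
                 train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = stratified),
            class = "split_assignment")
}

#' Fusion / screening configuration
#'
#' @param correlation_measure only `"point_biserial"` (Pearson correlation of
#'   a numeric feature with the binary label).
#' @param threshold absolute-correlation cutoff for keeping a feature, in
#'   \[0, 1).
#' @param svm_kernel `"rbf"` or `"linear"`.
#' @param svm_C SVM regularisation (cost).
#' @param use_embedding fuse the CNN penultimate embedding (default) or its
#'   output probability.
#' @param seed RNG seed (the SVM probability model uses internal
#'   cross-validation).
#' @export
fusion_config <- function(correlation_measure = "point_biserial", threshold = 0.3,
                          svm_kernel = c("rbf", "linear"), svm_C = 1,
                          use_embedding = TRUE, seed = 1L) {
  svm_kernel <- match.arg(svm_kernel)
  if (correlation_measure != "point_biserial")
    stop_config("unsupported correlation measure '%s'", correlation_measure)
  if (threshold < 0 || threshold >= 1) stop_config("threshold must be in [0, 1)")
  structure(list(correlation_measure = correlation_measure, threshold = threshold,
                 svm_kernel = svm_kernel, svm_C = svm_C,
                 use_embedding = use_embedding, seed = as.integer(seed)),
            class = "fusion_config")
}

#' Screen tabular features by point-biserial correlation with the label
#'
#' Must be called on the training partition only. Zero-variance features have
#' their correlation defined as 0 and are dropped with a warning.
#'
#' @param features data.frame or matrix of numeric features (columns named).
#' @param labels binary 0/1 vector.
#' @param config a [fusion_config()] supplying the threshold.
#' @return list with `selected` (names of kept features) and `correlations`
#'   (named vector over all features).
#' @export
screen_features <- function(features, labels, config = fusion_config()) {
  features <- as.data.frame(features)
  if (ncol(features) < 1L) stop_config("need at least one feature")
  if (length(unique(labels)) < 2L) stop_config("both classes required for screening")
  labels <- as.numeric(labels)
  cors <- vapply(features, function(f) {
    if (stats::sd(f) == 0) {
      warning("zero-variance feature dropped from screening")
      return(0)
    }
    stats::cor(as.numeric(f), labels)
  }, 0)
  list(selected = names(cors)[abs(cors) >= config$threshold],
       correlations = cors)
}

standardizer_fit <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(mu = mu, sd = sg)
}

standardizer_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, `/`)
}

#' Fit the fused SVM over CNN outputs and screened cluster features
#'
#' Concatenates the CNN embedding (or its output probability, per config)
#' with the selected cluster-validity features, standardises both with
#' training-set statistics, and fits a probability SVM. With every cluster
#' feature screened out, the model degenerates gracefully to an SVM on the
#' CNN representation alone.
#'
#' @param cnn_outputs numeric matrix (samples x embedding dims) or vector of
#'   probabilities, training partition only.
#' @param cluster_features data.frame of screened cluster features (training
#'   partition; may have zero columns).
#' @param labels binary 0/1 training labels.
#' @param config a [fusion_config()].
#' @return a `fused_model`; use [predict.fused_model()] for probabilities.
#' @export
fuse_and_fit_svm <- function(cnn_outputs, cluster_features, labels,
                             config = fusion_config()) {
  X1 <- as.matrix(cnn_outputs)
  X2 <- as.matrix(as.data.frame(cluster_features))
  if (nrow(X1) != length(labels) ||
      (ncol(X2) > 0 && nrow(X2) != length(labels)))
    stop_config("feature sources and labels are misaligned")
  X <- if (ncol(X2) > 0) cbind(X1, X2) else X1
  st <- standardizer_fit(X)
  Xs <- standardizer_apply(X, st)
  y <- factor(labels, levels = c(0, 1))
  fit <- with_local_seed(config$seed, {
    e1071::svm(Xs, y,
               kernel = if (config$svm_kernel == "rbf") "radial" else "linear",
               cost = config$svm_C, scale = FALSE)
  })
  # Platt calibration of the decision values, fitted on the training
  # partition with the usual regularized targets; deterministic, and the
  # sign of the margin is learned rather than assumed
  dec <- as.numeric(attr(stats::predict(fit, Xs, decision.values = TRUE),
                         "decision.values"))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  target <- ifelse(labels == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  platt <- suppressWarnings(
    stats::glm(target ~ dec, family = stats::quasibinomial())
  )
  structure(list(svm = fit, platt = stats::coef(platt), standardizer = st,
                 n_cnn = ncol(X1), n_cluster = ncol(X2), config = config),
            class = "fused_model")
}

#' Predict fused-model probabilities
#'
#' @param object a `fused_model`.
#' @param cnn_outputs,cluster_features feature sources for the new samples,
#'   with the same columns as at fit time.
#' @param ... unused.
#' @return vector of positive-class probabilities.
#' @export
predict.fused_model <- function(object, cnn_outputs, cluster_features = NULL, ...) {
  X1 <- as.matrix(cnn_outputs)
  X <- if (object$n_cluster > 0) {
    cbind(X1, as.matrix(as.data.frame(cluster_features)))
  } else X1
  if (ncol(X) != length(object$standardizer$mu))
    stop_config("prediction features have %d columns, expected %d",
                ncol(X), length(object$standardizer$mu))
  Xs <- standardizer_apply(X, object$standardizer)
  dec <- as.numeric(attr(stats::predict(object$svm, Xs, decision.values = TRUE),
                         "decision.values"))
  as.numeric(stats::plogis(object$platt[1] + object$platt[2] * dec))
}
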