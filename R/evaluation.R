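# Classifier evaluation: ROC/AUC with confidence intervals, sensitivity and
# specificity, and calibration curves.

check_preds <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_config("scores and labels differ in length")
  if (any(!is.finite(scores))) stop_config("scores must be finite")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_config("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop_config("AUC-type metrics are undefined with a single class")
  labels
}

#' Area under the ROC curve (pairwise Mann-Whitney form)
#'
#' The fraction of (positive, negative) pairs in which the positive sample
#' scores higher, with ties counted one half — computed from midranks, which
#' is algebraically identical to the pairwise definition.
#'
#' @param scores numeric prediction scores (any monotone scale).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_preds(scores, labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered from the (0,0)
#'   to the (1,1) corner; thresholds are the distinct scores (prediction is
#'   positive when `score >= threshold`).
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_preds(scores, labels)
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' AUC by trapezoidal integration of the empirical ROC curve
#'
#' Independent of [roc_auc()]'s rank computation; the two agree to machine
#' precision on any input (a classical identity between the Mann-Whitney
#' statistic and the area under the empirical ROC).
#'
#' @inheritParams roc_auc
#' @export
roc_auc_trapezoid <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Confidence interval for the AUC
#'
#' Default is a stratified bootstrap percentile interval: positives and
#' negatives are resampled separately (so every resample retains both
#' classes), the AUC recomputed, and the interval taken from the resample
#' quantiles. `method = "delong"` delegates to the asymptotic DeLong variance
#' method of \pkg{pROC} as an alternative.
#'
#' @inheritParams roc_auc
#' @param method `"bootstrap"` (default) or `"delong"`.
#' @param n_boot bootstrap resamples (>= 100).
#' @param seed RNG seed for resampling; fixed seed gives a fixed interval.
#' @param level confidence level (default 0.95).
#' @return list with `ci_low`, `ci_high`, `auc`, `method`.
#' @export
auc_confidence_interval <- function(scores, labels, method = c("bootstrap", "delong"),
                                    n_boot = 2000L, seed = 1L, level = 0.95) {
  method <- match.arg(method)
  labels <- check_preds(scores, labels)
  point <- roc_auc(scores, labels)
  alpha <- (1 - level) / 2
  if (method == "delong") {
    ci <- pROC::ci.auc(response = labels, predictor = scores,
                       method = "delong", conf.level = level,
                       levels = c(0, 1), direction = "<", quiet = TRUE)
    return(list(ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                auc = point, method = method))
  }
  if (n_boot < 100L) stop_config("n_boot must be >= 100")
  ip <- which(labels == 1L); im <- which(labels == 0L)
  aucs <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(ip[sample.int(length(ip), replace = TRUE)],
               im[sample.int(length(im), replace = TRUE)])
      roc_auc(scores[idx], labels[idx])
    }, 0)
  })
  q <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(ci_low = q[1], ci_high = q[2], auc = point, method = method)
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' A sample is predicted positive when `score >= threshold`. With
#' `optimize = TRUE` the threshold maximising Youden's J (sensitivity +
#' specificity - 1) over the observed scores is used instead (lowest such
#' threshold on ties) — only ever on the same partition, and reported.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold (default 0.5).
#' @param optimize pick the Youden-optimal threshold from these data.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `threshold`.
#' @export
sensitivity_specificity <- function(scores, labels, threshold = 0.5,
                                    optimize = FALSE) {
  labels <- check_preds(scores, labels)
  if (optimize) {
    cand <- sort(unique(scores))
    j <- vapply(cand, function(t) {
      sens <- sum(scores >= t & labels == 1L) / sum(labels == 1L)
      spec <- sum(scores < t & labels == 0L) / sum(labels == 0L)
      sens + spec - 1
    }, 0)
    threshold <- cand[which.max(j)]
  }
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1L); fn <- sum(!pos & labels == 1L)
  tn <- sum(!pos & labels == 0L); fp <- sum(pos & labels == 0L)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(labels), threshold = threshold)
}

#' Calibration curve
#'
#' Scores are cut into `n_bins` equal-width bins on \[0, 1\]; each occupied
#' bin reports the mean predicted probability, the observed positive
#' fraction, and the count. Empty bins are omitted.
#'
#' @param scores probabilities in \[0, 1\].
#' @param labels binary 0/1 labels.
#' @param n_bins number of bins (>= 2).
#' @return data.frame with `mean_predicted`, `observed_fraction`, `count`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  if (n_bins < 2L) stop_config("n_bins must be >= 2")
  if (any(scores < 0 | scores > 1)) stop_config("calibration requires scores in [0, 1]")
  labels <- as.integer(labels)
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  occupied <- sort(unique(bin))
  out <- do.call(rbind, lapply(occupied, function(bb) {
    i <- bin == bb
    data.frame(mean_predicted = mean(scores[i]),
               observed_fraction = mean(labels[i]),
               count = sum(i))
  }))
  rownames(out) <- NULL
  out
}

#' Full evaluation report for one prediction set
#'
#' @inheritParams auc_confidence_interval
#' @param threshold decision threshold for sensitivity/specificity/accuracy.
#' @param n_bins calibration bins.
#' @return an `evaluation_report`: accuracy, auc, ci_low/ci_high,
#'   sensitivity, specificity, threshold, calibration_bins, n.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5,
                                 method = "bootstrap", n_boot = 2000L,
                                 seed = 1L, n_bins = 10L) {
  labels <- check_preds(scores, labels)
  ss <- sensitivity_specificity(scores, labels, threshold = threshold)
  ci <- auc_confidence_interval(scores, labels, method = method,
                                n_boot = n_boot, seed = seed)
  structure(
    list(accuracy = ss$accuracy, auc = ci$auc,
         ci_low = ci$ci_low, ci_high = ci$ci_high,
         sensitivity = ss$sensitivity, specificity = ss$specificity,
         threshold = ss$threshold,
         calibration_bins = calibration_curve(scores, labels, n_bins),
         n = length(labels)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation (n = %d, threshold = %.3g)\n", x$n, x$threshold))
  cat(sprintf("  accuracy    %.4f\n", x$accuracy))
  cat(sprintf("  AUC         %.4f  (95%% CI %.4f-%.4f)\n", x$auc, x$ci_low, x$ci_high))
  cat(sprintf("  sensitivity %.4f\n", x$sensitivity))
  cat(sprintf("  specificity %.4f\n", x$specificity))
  invisible(x)
}
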