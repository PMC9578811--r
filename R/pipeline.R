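# End-to-end orchestration: phantom cohort -> denoise -> GMM segmentation ->
# validity features -> wavelet feature maps -> split -> residual CNN ->
# screening + SVM fusion -> evaluation, under one config and one global seed.

#' Pipeline run configuration
#'
#' A single global seed is fanned out deterministically to every stage
#' (cohort generation, per-sample GMM restarts, the split, CNN training,
#' the SVM probability model, bootstrap CIs), so a config fully determines
#' every output in single-threaded mode.
#'
#' @param cohort a [cohort_spec()] describing the synthetic cohort, or `NULL`
#'   when `samples` are passed to [run_pipeline()] directly.
#' @param denoise list with `method` and `width` for [denoise_volume()].
#' @param gmm a [gmm_config()].
#' @param dwt a [dwt_config()]; the default uses 32-pixel feature maps to
#'   match the tiny residual preset.
#' @param resnet a [resnet_config()]; default [resnet_preset()] `"tiny"`.
#' @param fusion a [fusion_config()].
#' @param train_fraction training share of the cohort (default 0.7).
#' @param threshold decision threshold for the reports.
#' @param n_boot bootstrap resamples for the AUC confidence intervals.
#' @param seed global seed.
#' @param out_dir optional directory; when given, the features table (CSV),
#'   training history (CSV), reports (JSON) and manifest (JSON) are written.
#' @export
run_config <- function(cohort = cohort_spec(),
                       denoise = list(method = "gaussian", width = 1),
                       gmm = gmm_config(),
                       dwt = dwt_config(target_size = 32L),
                       resnet = resnet_preset("tiny"),
                       fusion = fusion_config(),
                       train_fraction = 0.7, threshold = 0.5,
                       n_boot = 2000L, seed = 7L, out_dir = NULL) {
  structure(list(cohort = cohort, denoise = denoise, gmm = gmm, dwt = dwt,
                 resnet = resnet, fusion = fusion,
                 train_fraction = train_fraction, threshold = threshold,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @param samples optional pre-built list of `phantom_sample`s (or real
#'   volume/mask/label triples in the same structure); when `NULL` the
#'   cohort in the config is generated.
#' @return list with `train_report` and `test_report`
#'   ([evaluate_predictions()] objects), `features` (per-sample validity
#'   features), `screen` (screening correlations), `history` (CNN training
#'   history), `split`, `predictions` and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), samples = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  if (is.null(samples)) {
    cs <- config$cohort
    cs$seed <- derive_seed(seed, "phantom")
    samples <- generate_cohort(cs)
  }
  ids <- vapply(seq_along(samples), function(i) {
    if (!is.null(samples[[i]]$sample_id)) samples[[i]]$sample_id else sprintf("S%04d", i)
  }, "")
  labels <- vapply(samples, function(s) as.integer(s$node_label), 0L)
  names(labels) <- ids

  # --- subregion segmentation and validity features -------------------------
  gmm <- config$gmm
  gmm$seed <- derive_seed(seed, "gmm")
  features <- cohort_cluster_features(samples, gmm = gmm,
                                      denoise_method = config$denoise$method,
                                      denoise_width = config$denoise$width)

  # --- wavelet feature maps -------------------------------------------------
  maps <- lapply(samples, function(s) {
    feature_map_from_sample(s$volume, s$mask, config$dwt)
  })

  # --- split ----------------------------------------------------------------
  split <- split_dataset(ids, labels, train_fraction = config$train_fraction,
                         seed = derive_seed(seed, "split"), stratified = TRUE)
  tr <- match(split$train_ids, ids)
  te <- match(split$test_ids, ids)

  # --- residual CNN on the training partition -------------------------------
  rc_cfg <- config$resnet
  rc_cfg$seed <- derive_seed(seed, "resnet")
  rc_cfg$input_size <- config$dwt$target_size
  classifier <- build_residual_classifier(rc_cfg)
  classifier <- train_classifier(classifier, maps[tr], labels[tr])

  cnn_repr <- function(idx) {
    if (config$fusion$use_embedding) {
      predict(classifier, maps[idx], type = "embedding")
    } else {
      matrix(predict(classifier, maps[idx], type = "prob"), ncol = 1)
    }
  }

  # --- screening + fusion (training partition only) -------------------------
  fcfg <- config$fusion
  fcfg$seed <- derive_seed(seed, "svm")
  tab <- features[, c("chi", "silhouette", "dbi")]
  scr <- screen_features(tab[tr, , drop = FALSE], labels[tr], fcfg)
  fused <- fuse_and_fit_svm(cnn_repr(tr), tab[tr, scr$selected, drop = FALSE],
                            labels[tr], fcfg)
  score_tr <- predict(fused, cnn_repr(tr), tab[tr, scr$selected, drop = FALSE])
  score_te <- predict(fused, cnn_repr(te), tab[te, scr$selected, drop = FALSE])

  # --- evaluation -----------------------------------------------------------
  train_report <- evaluate_predictions(score_tr, labels[tr],
                                       threshold = config$threshold,
                                       n_boot = config$n_boot,
                                       seed = derive_seed(seed, "ci-train"))
  test_report <- evaluate_predictions(score_te, labels[te],
                                      threshold = config$threshold,
                                      n_boot = config$n_boot,
                                      seed = derive_seed(seed, "ci-test"))

  predictions <- data.frame(
    sample_id = c(ids[tr], ids[te]),
    partition = rep(c("train", "test"), c(length(tr), length(te))),
    score = c(score_tr, score_te),
    label = c(labels[tr], labels[te]),
    stringsAsFactors = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("petlnm")),
    seed = seed,
    stage_seeds = list(phantom = derive_seed(seed, "phantom"),
                       gmm = derive_seed(seed, "gmm"),
                       split = derive_seed(seed, "split"),
                       resnet = derive_seed(seed, "resnet"),
                       svm = derive_seed(seed, "svm")),
    config_hash = hash_object(config[setdiff(names(config), "out_dir")]),
    stage_hashes = list(features = hash_object(features),
                        maps = hash_object(maps),
                        split = hash_object(split[c("train_ids", "test_ids")]),
                        cnn_history = hash_object(classifier$history),
                        predictions = hash_object(predictions)),
    timestamp = format(Sys.time(), tz = "UTC"))

  result <- list(train_report = train_report, test_report = test_report,
                 features = features, screen = scr,
                 history = classifier$history, split = split,
                 predictions = predictions, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(classifier$history, file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    utils::write.csv(predictions, file.path(config$out_dir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(train = unclass(train_report), test = unclass(test_report)),
      file.path(config$out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
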