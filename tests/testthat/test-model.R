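test_that("the 0.7 split of 224 samples reproduces the 157/67 partition", {
  ids <- sprintf("P%03d", 1:224)
  labels <- rep(c(1L, 0L), c(106L, 118L)) # 74+32 positive, 83+35 negative
  sp <- split_dataset(ids, labels, train_fraction = 0.7, seed = 5)
  expect_length(sp$train_ids, 157L)
  expect_length(sp$test_ids, 67L)
  # stratification preserves class totals: 74 positive / 83 negative in train
  tr_lab <- labels[match(sp$train_ids, ids)]
  expect_identical(sum(tr_lab == 1L), 74L)
  expect_identical(sum(tr_lab == 0L), 83L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
})

test_that("split sizes, determinism and guards", {
  ids <- letters[1:10]
  labels <- rep(c(0L, 1L), 5)
  sp <- split_dataset(ids, labels, train_fraction = 0.7, seed = 1)
  expect_length(sp$train_ids, 7L)
  expect_length(sp$test_ids, 3L)
  expect_identical(split_dataset(ids, labels, seed = 1)$train_ids, sp$train_ids)
  expect_false(identical(split_dataset(ids, labels, seed = 2)$train_ids, sp$train_ids))
  expect_error(split_dataset(ids, labels, train_fraction = 1), "empties")
  full <- split_dataset(ids, labels, train_fraction = 1, allow_empty_test = TRUE)
  expect_length(full$train_ids, 10L)
  expect_error(split_dataset(ids, rep(1L, 10)), "both classes")
  expect_error(split_dataset(letters[1:3], c(0, 1, 0)), "at least 4")
})

test_that("feature screening keeps label-linked features and drops constants", {
  set.seed(40)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  feats <- data.frame(perfect = y,
                      informative = y + rnorm(n, sd = 0.5),
                      noise = rnorm(n),
                      flat = rep(2, n))
  expect_warning(scr <- screen_features(feats, y, fusion_config(threshold = 0.3)),
                 "zero-variance")
  expect_true(all(c("perfect", "informative") %in% scr$selected))
  expect_false("flat" %in% scr$selected)
  expect_equal(unname(scr$correlations["perfect"]), 1, tolerance = 1e-12)
  expect_identical(unname(scr$correlations["flat"]), 0)
})

test_that("fusion carries tabular signal even with a dead CNN embedding", {
  set.seed(41)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  emb <- matrix(0, n, 8) # zeroed embedding: no image signal
  tab <- data.frame(chi = y * 2 + rnorm(n, sd = 0.6))
  tr <- c(1:40, 61:100)
  te <- setdiff(seq_len(n), tr)
  fit <- fuse_and_fit_svm(emb[tr, ], tab[tr, , drop = FALSE], y[tr], fusion_config(seed = 2))
  auc <- roc_auc(predict(fit, emb[te, ], tab[te, , drop = FALSE]), y[te])
  expect_gt(auc, 0.75) # well above 0.5 + 3 SE at this test size
})

test_that("fusion degenerates gracefully when all cluster features are screened out", {
  set.seed(42)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  emb <- matrix(rnorm(n * 4), n, 4)
  emb[y == 1, 1] <- emb[y == 1, 1] + 2
  none <- data.frame()[seq_len(n), , drop = FALSE]
  fit <- fuse_and_fit_svm(emb, none, y, fusion_config(seed = 3))
  expect_identical(fit$n_cluster, 0L)
  p <- predict(fit, emb)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(roc_auc(p, y), 0.8)
})

test_that("test-partition labels never influence fitting or test predictions", {
  set.seed(43)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  emb <- matrix(rnorm(n * 4), n, 4)
  tab <- data.frame(chi = y + rnorm(n, sd = 0.8), dbi = rnorm(n))
  ids <- seq_len(n)
  sp <- split_dataset(ids, y, seed = 9)
  tr <- sp$train_ids
  te <- sp$test_ids

  fit_and_predict <- function(lab_vec) {
    scr <- screen_features(tab[tr, ], lab_vec[tr], fusion_config(threshold = 0.2, seed = 4))
    fit <- fuse_and_fit_svm(emb[tr, ], tab[tr, scr$selected, drop = FALSE],
                            lab_vec[tr], fusion_config(seed = 4))
    predict(fit, emb[te, ], tab[te, scr$selected, drop = FALSE])
  }
  y_shuffled_test <- y
  y_shuffled_test[te] <- sample(y[te])
  expect_identical(fit_and_predict(y), fit_and_predict(y_shuffled_test))
})

test_that("misaligned fusion inputs raise an error", {
  emb <- matrix(0, 10, 2)
  expect_error(fuse_and_fit_svm(emb, data.frame(a = 1:9), rep(c(0, 1), 5)),
               "misaligned")
})
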