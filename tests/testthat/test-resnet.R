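test_that("identity blocks with zeroed weights are exact pass-throughs", {
  cfg <- resnet_config(input_size = 8L, stem_width = 4L, stage_widths = 4L,
                       blocks_per_stage = 2L, stage_strides = 1L, seed = 2)
  cl <- build_residual_classifier(cfg)
  blk <- cl$params$stages[[1]][[2]]
  expect_null(blk$proj) # identity block: plain skip, no projection
  blk$conv1$W[] <- 0; blk$conv1$b[] <- 0
  blk$conv2$W[] <- 0; blk$conv2$b[] <- 0
  x <- array(abs(rnorm(8 * 8 * 4)), c(8, 8, 4)) # nonnegative, post-ReLU regime
  out <- petlnm:::block_fwd(x, blk, cl$cache)$out
  expect_identical(out, x)
})

test_that("the tiny preset maps a 224x224x3 input to one probability", {
  cl <- build_residual_classifier(resnet_preset("tiny"))
  x <- array(runif(224 * 224 * 3), c(224, 224, 3))
  p <- predict(cl, list(x))
  expect_length(p, 1L)
  expect_true(p >= 0 && p <= 1)
})

test_that("the resnet50 preset dwarfs tiny by over 100x in parameters", {
  n_tiny <- count_parameters(build_residual_classifier(resnet_preset("tiny")))
  big <- resnet_preset("resnet50")
  expect_identical(big$blocks_per_stage, c(3L, 4L, 6L, 3L))
  n_big <- count_parameters(build_residual_classifier(big))
  expect_gt(n_big / n_tiny, 100)
})

test_that("backpropagated gradients match numerical differentiation", {
  cfg <- resnet_config(input_size = 6L, in_channels = 2L, stem_width = 3L,
                       stage_widths = 3L, blocks_per_stage = 2L,
                       stage_strides = 2L, seed = 4)
  cl <- build_residual_classifier(cfg)
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  y <- 1
  fw <- petlnm:::net_fwd(cl$params, x, cl$cache)
  g <- petlnm:::net_bwd(cl$params, fw, fw$prob - y)
  loss <- function(p) {
    pp <- petlnm:::net_fwd(p, x, cl$cache)$prob
    -(y * log(pp) + (1 - y) * log(1 - pp))
  }
  eps <- 1e-6
  # probe representative weights in every layer type
  p <- cl$params; p$stem$W[5] <- p$stem$W[5] + eps
  expect_equal((loss(p) - loss(cl$params)) / eps, g$stem$W[5], tolerance = 1e-4)
  p <- cl$params; p$fc$W[1] <- p$fc$W[1] + eps
  expect_equal((loss(p) - loss(cl$params)) / eps, g$fc$W[1], tolerance = 1e-4)
  p <- cl$params; p$stages[[1]][[1]]$proj$W[2] <- p$stages[[1]][[1]]$proj$W[2] + eps
  expect_equal((loss(p) - loss(cl$params)) / eps,
               g$stages[[1]][[1]]$proj$W[2], tolerance = 1e-4)
  p <- cl$params; p$stages[[1]][[2]]$conv2$W[3] <- p$stages[[1]][[2]]$conv2$W[3] + eps
  expect_equal((loss(p) - loss(cl$params)) / eps,
               g$stages[[1]][[2]]$conv2$W[3], tolerance = 1e-4)
})

test_that("training on strong planted signal reaches high accuracy", {
  set.seed(9)
  y <- rep(c(0, 1), each = 20)
  maps <- lapply(y, signal_map)
  cl <- build_residual_classifier(resnet_preset("tiny", epochs = 8L, seed = 11))
  cl <- train_classifier(cl, maps, y)
  expect_gte(tail(cl$history$train_acc, 1), 0.9)
  expect_identical(nrow(cl$history), 8L)
  expect_true(all(c("train_loss", "train_acc", "val_loss", "val_acc") %in%
                    names(cl$history)))
})

test_that("training is deterministic and rejects degenerate inputs", {
  set.seed(10)
  y <- rep(c(0, 1), 8)
  maps <- lapply(y, signal_map, size = 16L)
  cfg <- resnet_preset("tiny", input_size = 16L, epochs = 2L, seed = 5)
  h1 <- train_classifier(build_residual_classifier(cfg), maps, y)$history
  h2 <- train_classifier(build_residual_classifier(cfg), maps, y)$history
  expect_identical(h1, h2)
  expect_error(train_classifier(build_residual_classifier(cfg), maps, rep(1, 16)),
               "both classes")
  bad <- lapply(rep(0, 4), signal_map, size = 8L)
  expect_error(train_classifier(build_residual_classifier(cfg), bad, c(0, 1, 0, 1)),
               "expects")
})

test_that("training on label noise yields chance-level held-out AUC", {
  set.seed(12)
  y_tr <- sample(rep(c(0, 1), each = 15))
  maps_tr <- lapply(rep(0, 30), signal_map, size = 16L) # featureless class-0 maps
  cl <- build_residual_classifier(resnet_preset("tiny", input_size = 16L,
                                                epochs = 4L, seed = 6))
  cl <- train_classifier(cl, maps_tr, y_tr)
  maps_te <- lapply(rep(0, 30), signal_map, size = 16L)
  y_te <- sample(rep(c(0, 1), each = 15))
  auc <- roc_auc(predict(cl, maps_te), y_te)
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})
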