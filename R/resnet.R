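# A small residual convolutional network for binary classification of
# wavelet feature maps, implemented directly on R matrix algebra.
#
# Architecture: 3x3 stem convolution, then stages of residual blocks. Each
# stage opens with a convolutional block (3x3 stride-s conv -> ReLU -> 3x3
# conv, plus a 1x1 projection shortcut) followed by identity blocks (same,
# stride 1, plain skip). Global average pooling, dropout, and a single
# sigmoid unit close the network. Convolutions are evaluated as im2col
# matrix products; gradients are exact backpropagation; optimisation is Adam
# on mean binary cross-entropy.

#' Residual network configuration
#'
#' @param input_size square input side length in pixels.
#' @param in_channels input channels (3 for LL/LH/HL feature maps).
#' @param stem_width channels of the stem convolution.
#' @param stage_widths channel count per stage.
#' @param blocks_per_stage residual blocks per stage (first is the
#'   projection-shortcut conv block, the rest identity blocks).
#' @param stage_strides spatial stride of each stage's conv block.
#' @param dropout_rate dropout probability on the pooled embedding, in \[0,1).
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param seed RNG seed for weight init, shuffling and dropout.
#' @export
resnet_config <- function(input_size = 32L, in_channels = 3L, stem_width = 8L,
                          stage_widths = c(8L, 16L), blocks_per_stage = c(2L, 2L),
                          stage_strides = c(2L, 2L), dropout_rate = 0.2,
                          epochs = 12L, batch_size = 8L, learning_rate = 3e-3,
                          seed = 1L) {
  if (length(stage_widths) < 1L) stop_config("at least one stage is required")
  if (length(blocks_per_stage) != length(stage_widths) ||
      length(stage_strides) != length(stage_widths))
    stop_config("stage_widths, blocks_per_stage and stage_strides must align")
  if (any(blocks_per_stage < 1L)) stop_config("each stage needs >= 1 block")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_config("dropout_rate must be in [0,1)")
  if (input_size < prod(stage_strides))
    stop_config("input size %d is smaller than the total downsampling factor %d",
                input_size, prod(stage_strides))
  structure(list(input_size = as.integer(input_size), in_channels = as.integer(in_channels),
                 stem_width = as.integer(stem_width), stage_widths = as.integer(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 stage_strides = as.integer(stage_strides), dropout_rate = dropout_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "resnet_config")
}

#' Named residual-network presets
#'
#' `"tiny"` is the desk-scale default used throughout the pipeline and tests.
#' `"resnet50"` reproduces the canonical large-network stage layout
#' (3, 4, 6, 3 blocks at widths 64/128/256/512 on 224-pixel input); it is
#' provided for architectural fidelity and parameter-count comparisons, not
#' for desk-scale training.
#'
#' @param name `"tiny"` or `"resnet50"`.
#' @param ... overrides forwarded to [resnet_config()].
#' @export
resnet_preset <- function(name = c("tiny", "resnet50"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    tiny = list(input_size = 32L, stem_width = 8L, stage_widths = c(8L, 16L),
                blocks_per_stage = c(2L, 2L), stage_strides = c(2L, 2L),
                dropout_rate = 0.2, epochs = 12L, learning_rate = 3e-3),
    resnet50 = list(input_size = 224L, stem_width = 64L,
                    stage_widths = c(64L, 128L, 256L, 512L),
                    blocks_per_stage = c(3L, 4L, 6L, 3L),
                    stage_strides = c(1L, 2L, 2L, 2L),
                    dropout_rate = 0.5, epochs = 10L, learning_rate = 1e-3))
  do.call(resnet_config, utils::modifyList(defaults, list(...)))
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

new_conv <- function(k, cin, cout) {
  list(W = he_init(k * k * cin, cout, k * k * cin), b = numeric(cout), k = k)
}

#' Build an untrained residual classifier
#'
#' Weights are He-initialized under the config seed, so building twice with
#' the same config yields identical networks.
#'
#' @param config a [resnet_config()] or [resnet_preset()].
#' @return object of class `residual_classifier`.
#' @export
build_residual_classifier <- function(config = resnet_preset("tiny")) {
  stopifnot(inherits(config, "resnet_config"))
  with_local_seed(config$seed, {
    cin <- config$in_channels
    params <- list(stem = new_conv(3L, cin, config$stem_width))
    cin <- config$stem_width
    stages <- list()
    for (s in seq_along(config$stage_widths)) {
      w <- config$stage_widths[s]
      blocks <- list()
      for (b in seq_len(config$blocks_per_stage[s])) {
        first <- b == 1L
        stride <- if (first) config$stage_strides[s] else 1L
        blk <- list(conv1 = new_conv(3L, cin, w), conv2 = new_conv(3L, w, w),
                    stride = stride)
        if (first && (stride != 1L || cin != w)) blk$proj <- new_conv(1L, cin, w)
        blocks[[b]] <- blk
        cin <- w
      }
      stages[[s]] <- blocks
    }
    params$stages <- stages
    params$fc <- list(W = matrix(stats::rnorm(cin, 0, 1 / sqrt(cin)), cin, 1),
                      b = 0)
    structure(list(config = config, params = params,
                   cache = new.env(parent = emptyenv()), trained = FALSE),
              class = "residual_classifier")
  })
}

#' Total number of trainable parameters
#' @param classifier a `residual_classifier`.
#' @export
count_parameters <- function(classifier) {
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) n <<- n + length(x)
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(classifier$params)
  n
}

# ---- convolution primitives ------------------------------------------------

im2col_index <- function(cache, H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  if (!is.null(cache[[key]])) return(cache[[key]])
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  PI <- rep((seq_len(Ho) - 1L) * stride, times = Wo)
  PJ <- rep((seq_len(Wo) - 1L) * stride, each = Ho)
  idx <- matrix(0L, Ho * Wo, k * k * C)
  col <- 0L
  for (c in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    col <- col + 1L
    idx[, col] <- (c - 1L) * Hp * Wp + (PJ + dj - 1L) * Hp + (PI + di)
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  cache[[key]] <- out
  out
}

conv_fwd <- function(x, conv, stride, cache) {
  d <- dim(x)
  k <- conv$k
  pad <- if (k == 1L) 0L else 1L
  ic <- im2col_index(cache, d[1], d[2], d[3], k, stride, pad)
  if (pad > 0L) {
    xp <- array(0, c(ic$Hp, ic$Wp, d[3]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  } else xp <- x
  # flatten before subscripting: a matrix subscript with ncol == 3 would be
  # misread as per-dimension coordinates on a 3D array
  Xc <- matrix(xp[as.vector(ic$idx)], nrow(ic$idx), ncol(ic$idx))
  out <- Xc %*% conv$W
  out <- out + rep(conv$b, each = nrow(out))
  list(out = array(out, c(ic$Ho, ic$Wo, ncol(conv$W))), Xc = Xc, ic = ic,
       in_dim = d, pad = pad)
}

conv_bwd <- function(dout, fwd, conv) {
  ic <- fwd$ic
  dO <- matrix(dout, ic$Ho * ic$Wo, length(conv$b))
  dW <- crossprod(fwd$Xc, dO)
  db <- colSums(dO)
  dXc <- dO %*% t(conv$W)
  dxp <- numeric(ic$Hp * ic$Wp * fwd$in_dim[3])
  for (j in seq_len(ncol(ic$idx))) {
    jj <- ic$idx[, j]
    dxp[jj] <- dxp[jj] + dXc[, j]
  }
  dxp <- array(dxp, c(ic$Hp, ic$Wp, fwd$in_dim[3]))
  dx <- if (fwd$pad > 0L) {
    dxp[fwd$pad + seq_len(fwd$in_dim[1]), fwd$pad + seq_len(fwd$in_dim[2]), , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

block_fwd <- function(x, blk, cache) {
  f1 <- conv_fwd(x, blk$conv1, blk$stride, cache)
  h1 <- relu(f1$out)
  f2 <- conv_fwd(h1, blk$conv2, 1L, cache)
  if (!is.null(blk$proj)) {
    fp <- conv_fwd(x, blk$proj, blk$stride, cache)
    sc <- fp$out
  } else {
    fp <- NULL
    sc <- x
  }
  pre <- f2$out + sc
  list(out = relu(pre), pre = pre, f1 = f1, h1 = h1, f2 = f2, fp = fp, x = x)
}

block_bwd <- function(dout, bf, blk) {
  dpre <- dout * (bf$pre > 0)
  b2 <- conv_bwd(dpre, bf$f2, blk$conv2)
  dh1 <- b2$dx * (bf$h1 > 0)
  b1 <- conv_bwd(dh1, bf$f1, blk$conv1)
  g <- list(conv1 = list(W = b1$dW, b = b1$db), conv2 = list(W = b2$dW, b = b2$db))
  if (!is.null(blk$proj)) {
    bp <- conv_bwd(dpre, bf$fp, blk$proj)
    g$proj <- list(W = bp$dW, b = bp$db)
    dx <- b1$dx + bp$dx
  } else {
    dx <- b1$dx + dpre
  }
  list(dx = dx, grads = g)
}

net_fwd <- function(params, x, cache, drop_mask = NULL) {
  fs <- conv_fwd(x, params$stem, 1L, cache)
  h <- relu(fs$out)
  stage_acts <- list()
  for (s in seq_along(params$stages)) {
    acts <- list()
    for (b in seq_along(params$stages[[s]])) {
      bf <- block_fwd(h, params$stages[[s]][[b]], cache)
      acts[[b]] <- bf
      h <- bf$out
    }
    stage_acts[[s]] <- acts
  }
  spatial <- prod(dim(h)[1:2])
  emb <- apply(h, 3, mean)
  embd <- if (is.null(drop_mask)) emb else emb * drop_mask
  z <- sum(embd * params$fc$W) + params$fc$b
  p <- stats::plogis(z)
  list(prob = p, z = z, emb = emb, embd = embd, h_dim = dim(h),
       spatial = spatial, fs = fs, stage_acts = stage_acts)
}

net_bwd <- function(params, fwd, dz, drop_mask = NULL) {
  g <- list(fc = list(W = matrix(fwd$embd * dz, ncol = 1), b = dz))
  demb <- as.numeric(params$fc$W) * dz
  if (!is.null(drop_mask)) demb <- demb * drop_mask
  dh <- array(rep(demb / fwd$spatial, each = fwd$spatial), fwd$h_dim)
  g$stages <- vector("list", length(params$stages))
  for (s in rev(seq_along(params$stages))) {
    g$stages[[s]] <- vector("list", length(params$stages[[s]]))
    for (b in rev(seq_along(params$stages[[s]]))) {
      bb <- block_bwd(dh, fwd$stage_acts[[s]][[b]], params$stages[[s]][[b]])
      g$stages[[s]][[b]] <- bb$grads
      dh <- bb$dx
    }
  }
  dstem_out <- dh * (fwd$fs$out > 0)
  bs <- conv_bwd(dstem_out, fwd$fs, params$stem)
  g$stem <- list(W = bs$dW, b = bs$db)
  g
}

# elementwise tree arithmetic over nested parameter lists; named children are
# matched by name (grad trees may order siblings differently), unnamed by
# position
tree_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  nms <- names(a)
  if (is.null(nms)) {
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
  } else {
    for (nm in nms) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
  }
  out
}

tree_zero <- function(a) tree_map2(a, a, function(x, y) x * 0)

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mhat_scale <- 1 / (1 - beta1^t)
  vhat_scale <- 1 / (1 - beta2^t)
  delta <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
  })
  params <- tree_map2(params, delta, `-`)
  list(params = params, state = state)
}

# numeric leaves that Adam should update (weights/biases only); drops scalar
# structure fields like stride and kernel size
trainable <- function(x) {
  if (!is.list(x)) return(NULL)
  nms <- names(x)
  if (is.null(nms)) {
    return(lapply(x, trainable))
  }
  keep <- list()
  for (nm in nms) {
    if (nm %in% c("W", "b")) {
      keep[[nm]] <- x[[nm]]
    } else if (is.list(x[[nm]])) {
      sub <- trainable(x[[nm]])
      if (length(sub)) keep[[nm]] <- sub
    }
  }
  keep
}

merge_trainable <- function(params, upd) {
  nms <- names(upd)
  if (is.null(nms)) {
    for (i in seq_along(upd)) params[[i]] <- merge_trainable(params[[i]], upd[[i]])
    return(params)
  }
  for (nm in nms) {
    if (nm %in% c("W", "b")) params[[nm]] <- upd[[nm]]
    else params[[nm]] <- merge_trainable(params[[nm]], upd[[nm]])
  }
  params
}

as_map_array <- function(m) {
  if (inherits(m, "feature_map")) m$channels else m
}

#' Train the residual classifier
#'
#' Seeded end to end: weight initialisation (from the build), epoch
#' shuffling, dropout masks and the validation split all derive from
#' `classifier$config$seed`, so two runs with the same inputs produce
#' identical histories (single-threaded). A stratified validation fraction is
#' carved out of the supplied training samples; the checkpoint with the best
#' validation accuracy (earliest epoch on ties) is returned.
#'
#' @param classifier an untrained `residual_classifier`.
#' @param maps list of `feature_map`s (or raw H x W x C arrays).
#' @param labels binary 0/1 vector, one per map; both classes must appear.
#' @param validation_fraction fraction of samples held out for epoch-wise
#'   validation (stratified).
#' @return the classifier with trained weights (`$params` set to the best
#'   checkpoint) and `$history`, a data.frame with per-epoch train/validation
#'   loss and accuracy.
#' @export
train_classifier <- function(classifier, maps, labels, validation_fraction = 0.2) {
  stopifnot(inherits(classifier, "residual_classifier"))
  cfg <- classifier$config
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_config("training requires both classes to be present")
  if (length(maps) != length(labels))
    stop_config("maps (%d) and labels (%d) differ in length", length(maps), length(labels))
  xs <- lapply(maps, as_map_array)
  dims <- dim(xs[[1]])
  if (!identical(dims, c(cfg$input_size, cfg$input_size, cfg$in_channels)))
    stop_config("feature maps are %s but the network expects %dx%dx%d",
                paste(dims, collapse = "x"), cfg$input_size, cfg$input_size,
                cfg$in_channels)

  with_local_seed(derive_seed(cfg$seed, "train"), {
    n <- length(xs)
    val_idx <- integer(0)
    if (validation_fraction > 0 && n >= 8L) {
      for (cls in unique(labels)) {
        ic <- which(labels == cls)
        nv <- max(1L, round_half_up(length(ic) * validation_fraction))
        val_idx <- c(val_idx, sample(ic, nv))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(labels[tr_idx])) < 2L)
      stop_config("validation split left a single-class training set")

    params <- classifier$params
    tp <- trainable(params)
    state <- list(m = tree_zero(tp), v = tree_zero(tp))
    cache <- classifier$cache
    p_drop <- cfg$dropout_rate
    nf <- length(params$fc$W)
    best <- list(acc = -Inf, params = params, epoch = 0L)
    hist <- vector("list", cfg$epochs)
    t_step <- 0L

    eval_set <- function(prm, idx) {
      if (!length(idx)) return(c(NA_real_, NA_real_))
      loss <- 0; acc <- 0
      for (i in idx) {
        fw <- net_fwd(prm, xs[[i]], cache)
        p <- min(max(fw$prob, 1e-12), 1 - 1e-12)
        loss <- loss - (labels[i] * log(p) + (1 - labels[i]) * log(1 - p))
        acc <- acc + as.integer((p >= 0.5) == (labels[i] == 1L))
      }
      c(loss / length(idx), acc / length(idx))
    }

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_acc <- 0
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (batch in batches) {
        gacc <- NULL
        for (i in batch) {
          mask <- if (p_drop > 0) {
            (stats::runif(nf) >= p_drop) / (1 - p_drop)
          } else NULL
          fw <- net_fwd(params, xs[[i]], cache, drop_mask = mask)
          p <- min(max(fw$prob, 1e-12), 1 - 1e-12)
          ep_loss <- ep_loss - (labels[i] * log(p) + (1 - labels[i]) * log(1 - p))
          ep_acc <- ep_acc + as.integer((p >= 0.5) == (labels[i] == 1L))
          g <- net_bwd(params, fw, fw$prob - labels[i], drop_mask = mask)
          gt <- trainable(g)
          gacc <- if (is.null(gacc)) gt else tree_map2(gacc, gt, `+`)
        }
        gacc <- tree_map2(gacc, gacc, function(x, y) x / length(batch))
        t_step <- t_step + 1L
        up <- adam_step(trainable(params), gacc, state, cfg$learning_rate, t_step)
        state <- up$state
        params <- merge_trainable(params, up$params)
      }
      val <- eval_set(params, val_idx)
      hist[[ep]] <- data.frame(epoch = ep,
                               train_loss = ep_loss / length(tr_idx),
                               train_acc = ep_acc / length(tr_idx),
                               val_loss = val[1], val_acc = val[2])
      score <- if (is.na(val[2])) ep_acc / length(tr_idx) else val[2]
      if (score > best$acc) best <- list(acc = score, params = params, epoch = ep)
    }
    classifier$params <- best$params
    classifier$final_params <- params
    classifier$history <- do.call(rbind, hist)
    classifier$best_epoch <- best$epoch
    classifier$trained <- TRUE
    classifier
  })
}

#' Predict with a residual classifier
#'
#' @param object a `residual_classifier`.
#' @param maps list of `feature_map`s or arrays.
#' @param type `"prob"` for the sigmoid output probability, `"embedding"` for
#'   the pooled penultimate-layer feature vector (one row per sample).
#' @param ... unused.
#' @export
predict.residual_classifier <- function(object, maps, type = c("prob", "embedding"), ...) {
  type <- match.arg(type)
  xs <- lapply(maps, as_map_array)
  if (type == "prob") {
    vapply(xs, function(x) net_fwd(object$params, x, object$cache)$prob, 0)
  } else {
    t(vapply(xs, function(x) net_fwd(object$params, x, object$cache)$emb,
             numeric(length(object$params$fc$W))))
  }
}
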