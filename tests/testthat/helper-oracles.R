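# Independent brute-force oracles, written as literal double/triple loops so
# they share no code with the package implementations they check.

oracle_chi <- function(x, lab) {
  K <- max(lab)
  N <- length(x)
  cg <- mean(x)
  between <- 0
  within <- 0
  for (k in seq_len(K)) {
    xs <- x[lab == k]
    ck <- mean(xs)
    between <- between + length(xs) * (ck - cg)^2
    for (xi in xs) within <- within + (xi - ck)^2
  }
  (between / (K - 1)) / (within / (N - K))
}

oracle_silhouette <- function(x, lab) {
  K <- max(lab)
  N <- length(x)
  s <- numeric(N)
  for (i in seq_len(N)) {
    own <- lab[i]
    mates <- which(lab == own & seq_len(N) != i)
    if (length(mates) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(abs(x[i] - x[mates]))
    b <- Inf
    for (k in seq_len(K)) {
      if (k == own) next
      b <- min(b, mean(abs(x[i] - x[lab == k])))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

oracle_dbi <- function(x, lab) {
  K <- max(lab)
  avg <- numeric(K)
  cen <- numeric(K)
  for (k in seq_len(K)) {
    xs <- x[lab == k]
    cen[k] <- mean(xs)
    m <- length(xs)
    tot <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) tot <- tot + abs(xs[i] - xs[j])
    avg[k] <- 2 / (m * (m - 1)) * tot
  }
  db <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (j == i) next
      worst <- max(worst, (avg[i] + avg[j]) / abs(cen[i] - cen[j]))
    }
    db <- db + worst
  }
  db / K
}

# pairwise Mann-Whitney AUC by explicit enumeration of (positive, negative)
# pairs, ties counted one half
oracle_auc_pairs <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (q in sn) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# dense 3D Gaussian convolution with clamped (edge-replicated) indices
oracle_gauss_conv3d <- function(vol, sd) {
  r <- max(1L, ceiling(3 * sd))
  k1 <- dnorm(seq(-r, r), sd = sd)
  k1 <- k1 / sum(k1)
  d <- dim(vol)
  out <- array(0, d)
  cl <- function(i, n) min(max(i, 1L), n)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      acc <- acc + k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1] *
        vol[cl(x + dx, d[1]), cl(y + dy, d[2]), cl(z + dz, d[3])]
    }
    out[x, y, z] <- acc
  }
  out
}

# random 1D labeled point set where every cluster has at least `min_size`
# members
random_labeled_set <- function(n, K, min_size = 2L) {
  lab <- c(rep(seq_len(K), each = min_size),
           sample(seq_len(K), n - K * min_size, replace = TRUE))
  lab <- sample(lab)
  x <- rnorm(n, mean = lab, sd = 0.8)
  list(x = x, lab = lab)
}
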