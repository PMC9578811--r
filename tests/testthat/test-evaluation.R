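test_that("AUC worked examples", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75, tolerance = 1e-12)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.2, 0.8), c(1, 1)), "single class")
})

test_that("rank, trapezoidal and brute-force pairwise AUC all agree", {
  set.seed(50)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2) # coarse grid forces ties
    a <- roc_auc(scores, labels)
    expect_equal(a, roc_auc_trapezoid(scores, labels), tolerance = 1e-12)
    expect_equal(a, oracle_auc_pairs(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and obeys symmetries", {
  set.seed(51)
  scores <- runif(30)
  labels <- sample(c(0, 1), 30, replace = TRUE)
  labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(qlogis(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(scores^3, labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(1 - scores, 1 - labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(scores, 1 - labels), 1 - a, tolerance = 1e-12)
})

test_that("our AUC matches the pROC reference implementation", {
  set.seed(52)
  scores <- runif(50)
  labels <- sample(c(0, 1), 50, replace = TRUE)
  labels[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(labels, scores, levels = c(0, 1),
                              direction = "<", quiet = TRUE))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("bootstrap confidence intervals: degenerate, deterministic, coherent", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c(0, 0, 1, 1)
  ci <- auc_confidence_interval(scores, labels, n_boot = 200, seed = 3)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))
  set.seed(53)
  s2 <- runif(60)
  l2 <- rbinom(60, 1, plogis(4 * (s2 - 0.5)))
  l2[1:2] <- c(0, 1)
  c1 <- auc_confidence_interval(s2, l2, n_boot = 300, seed = 7)
  c2 <- auc_confidence_interval(s2, l2, n_boot = 300, seed = 7)
  expect_identical(c1, c2)
  expect_lte(c1$ci_low, c1$auc)
  expect_gte(c1$ci_high, c1$auc)
  expect_error(auc_confidence_interval(s2, l2, n_boot = 50), "n_boot")
})

test_that("the DeLong alternative produces a coherent interval", {
  set.seed(54)
  s <- runif(80)
  l <- rbinom(80, 1, plogis(5 * (s - 0.5)))
  l[1:2] <- c(0, 1)
  ci <- auc_confidence_interval(s, l, method = "delong")
  expect_lte(ci$ci_low, ci$auc)
  expect_gte(ci$ci_high, ci$auc)
})

test_that("sensitivity/specificity worked examples", {
  r <- sensitivity_specificity(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(c(r$sensitivity, r$specificity, r$accuracy), c(1, 1, 1))
  r0 <- sensitivity_specificity(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0)
  expect_equal(c(r0$sensitivity, r0$specificity), c(1, 0))
  r2 <- sensitivity_specificity(c(0.6, 0.4, 0.55, 0.3), c(1, 1, 0, 0), 0.5)
  expect_equal(c(r2$sensitivity, r2$specificity, r2$accuracy), c(0.5, 0.5, 0.5))
  # Youden-optimal threshold on cleanly separated scores
  ry <- sensitivity_specificity(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), optimize = TRUE)
  expect_equal(ry$sensitivity + ry$specificity, 2)
  expect_equal(ry$threshold, 0.8)
})

test_that("calibration curves: single bin, hand count, simulation", {
  one <- calibration_curve(rep(0.5, 10), rep(c(0, 1), 5))
  expect_identical(nrow(one), 1L)
  expect_equal(one$mean_predicted, 0.5)
  expect_equal(one$observed_fraction, 0.5)

  two <- calibration_curve(c(rep(0.1, 4), rep(0.9, 4)), c(rep(0, 4), rep(1, 4)),
                           n_bins = 2)
  expect_equal(two$mean_predicted, c(0.1, 0.9))
  expect_equal(two$observed_fraction, c(0, 1))
  expect_equal(two$count, c(4L, 4L))

  set.seed(55)
  p <- runif(10000)
  y <- rbinom(10000, 1, p) # calibrated by construction
  cc <- calibration_curve(p, y, n_bins = 10)
  expect_lte(max(abs(cc$mean_predicted - cc$observed_fraction)), 0.05)
  expect_identical(sum(cc$count), 10000L)
  expect_error(calibration_curve(p, y, n_bins = 1), "n_bins")
})

test_that("the evaluation report bundles coherent fields", {
  set.seed(56)
  s <- runif(60)
  l <- rbinom(60, 1, plogis(6 * (s - 0.5)))
  l[1:2] <- c(0, 1)
  rep_ <- evaluate_predictions(s, l, n_boot = 200, seed = 1)
  expect_s3_class(rep_, "evaluation_report")
  expect_true(rep_$ci_low <= rep_$auc && rep_$auc <= rep_$ci_high)
  expect_true(all(c(rep_$accuracy, rep_$sensitivity, rep_$specificity) >= 0))
  expect_identical(sum(rep_$calibration_bins$count), 60L)
  expect_output(print(rep_), "AUC")
})
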