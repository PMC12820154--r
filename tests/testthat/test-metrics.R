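test_that("confusion counting is exact", {
  cm <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_identical(c(cm$tp, cm$tn, cm$fp, cm$fn), c(2L, 1L, 0L, 0L))
  # all-positive predictor: FP equals the number of negatives
  cm2 <- confusion(rep(c(0, 1), 5), rep(1, 10))
  expect_identical(cm2$fp, 5L)
  expect_identical(cm2$fn, 0L)
  expect_error(confusion(c(0, 1), c(1)), "length")
  expect_error(confusion(c(0, 2), c(1, 0)), "binary")
  # hand loop on random pairs
  withr::with_seed(71L, {
    y <- rbinom(50, 1, 0.4); p <- rbinom(50, 1, 0.6)
  })
  cm3 <- confusion(y, p)
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in 1:50) {
    if (y[i] == 1 && p[i] == 1) tp <- tp + 1L
    if (y[i] == 0 && p[i] == 1) fp <- fp + 1L
    if (y[i] == 0 && p[i] == 0) tn <- tn + 1L
    if (y[i] == 1 && p[i] == 0) fn <- fn + 1L
  }
  expect_identical(c(cm3$tp, cm3$fp, cm3$tn, cm3$fn), c(tp, fp, tn, fn))
})

test_that("the federated confusion counts reproduce the reported percentages", {
  # test-set counts: 384/390 pneumonia detected, 66 false positives
  rep <- classification_metrics(confusion_matrix(tp = 384, fp = 66,
                                                 tn = 168, fn = 6))
  p <- rep$percent
  expect_equal(p$accuracy, 88.46)
  expect_equal(p$pneumonia$recall, 98.46)
  expect_equal(p$pneumonia$precision, 85.33)
  expect_equal(p$pneumonia$f1, 91.43)
  expect_equal(p$normal$recall, 71.79)
  expect_equal(p$normal$precision, 96.55)
  expect_equal(p$normal$f1, 82.35)
  expect_false(rep$degenerate)
})

test_that("the centralized confusion counts reproduce the reported percentages", {
  rep <- classification_metrics(confusion_matrix(tp = 247, fp = 82,
                                                 tn = 152, fn = 143))
  p <- rep$percent
  expect_equal(p$accuracy, 63.94)
  expect_equal(p$pneumonia$recall, 63.33)
  expect_equal(p$pneumonia$precision, 75.08)
  expect_equal(p$pneumonia$f1, 68.71)
  expect_equal(p$normal$recall, 64.96)
  expect_equal(p$normal$precision, 51.53)
  expect_equal(p$normal$f1, 57.47)
})

test_that("F1 is the harmonic mean of the printed precision/recall pairs", {
  for (cm in list(confusion_matrix(384, 66, 168, 6),
                  confusion_matrix(247, 82, 152, 143))) {
    r <- classification_metrics(cm)
    for (cls in c("pneumonia", "normal")) {
      pr <- r[[cls]]$precision; rc <- r[[cls]]$recall
      expect_equal(ns$round_half_up(100 * r[[cls]]$f1, 2),
                   ns$round_half_up(100 * 2 * pr * rc / (pr + rc), 2))
    }
  }
})

test_that("degenerate confusion cells follow the zero convention", {
  rep <- classification_metrics(confusion_matrix(tp = 0, fp = 0,
                                                 tn = 5, fn = 3))
  expect_equal(rep$pneumonia$precision, 0)
  expect_true(rep$degenerate)
  expect_error(classification_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("AUC follows the rank statistic with half-credit ties", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  # brute force over all positive-negative pairs, ties worth 1/2
  withr::with_seed(72L, {
    s <- round(runif(30), 1)  # rounding forces ties
    y <- rbinom(30, 1, 0.5)
  })
  pos <- s[y == 1]; neg <- s[y == 0]
  brute <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(s, y), brute, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(3 * s), y), brute, tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(73L, {
    s <- runif(40); y <- rbinom(40, 1, 0.5)
  })
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-10)
})

test_that("average precision matches the per-positive precision mean", {
  # for distinct scores AP equals the mean over positives of precision at
  # each positive's own threshold
  withr::with_seed(74L, {
    s <- sample(seq(0.01, 0.99, by = 0.01), 25)
    y <- rbinom(25, 1, 0.4)
  })
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]
  precs <- cumsum(ys) / seq_along(ys)
  expect_equal(pr_average_precision(s, y), mean(precs[ys == 1]),
               tolerance = 1e-12)
  expect_equal(pr_average_precision(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
})

test_that("the Youden threshold maximises sensitivity + specificity - 1", {
  yt <- youden_threshold(c(0.1, 0.9), c(0, 1))
  expect_equal(yt$threshold, 0.9)  # tie broken toward the higher cutoff
  expect_equal(yt$J, 1.0)
  # exhaustive oracle on random data
  withr::with_seed(75L, {
    s <- round(runif(50), 2); y <- rbinom(50, 1, 0.5)
  })
  yt2 <- youden_threshold(s, y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  best_J <- -Inf; best_thr <- -Inf
  for (thr in sort(unique(s))) {
    pred <- as.integer(s >= thr)
    J <- sum(pred & y) / n1 + sum(!pred & !y) / n0 - 1
    if (J > best_J + 1e-12) { best_J <- J; best_thr <- thr }
    else if (J > best_J - 1e-12 && thr > best_thr) best_thr <- thr
  }
  expect_equal(yt2$J, best_J, tolerance = 1e-12)
  expect_gte(yt2$threshold, best_thr - 1e-12)
  # inverting labels attains the same maximal J at the complementary point
  yt_inv <- youden_threshold(-s, 1 - y)
  expect_equal(yt_inv$J, yt2$J, tolerance = 1e-12)
})

test_that("communication cost reproduces both published conventions", {
  expect_equal(ns$round_half_up(communication_cost(147456, 32, "binary_mib"), 2),
               0.56)
  expect_equal(ns$round_half_up(communication_cost(5672258, 32, "binary_mib"), 2),
               21.64)
  expect_equal(communication_cost(147456, 32, "decimal_eq12"), 0.589824,
               tolerance = 1e-12)
  # linear in count and in precision
  expect_equal(communication_cost(2 * 147456, 32, "decimal_eq12"),
               2 * communication_cost(147456, 32, "decimal_eq12"))
  expect_equal(communication_cost(147456, 64, "decimal_eq12"),
               2 * communication_cost(147456, 32, "decimal_eq12"))
  expect_error(communication_cost(100, 12), "bit_precision")
})

test_that("metric_report combines threshold and ranking views", {
  withr::with_seed(76L, {
    s <- c(runif(20, 0.4, 1), runif(20, 0, 0.6))
    y <- rep(c(1, 0), each = 20)
  })
  rep <- metric_report(s, y, threshold = 0.5)
  expect_equal(rep$auc_roc, roc_auc(s, y))
  expect_equal(rep$optimal_threshold, youden_threshold(s, y)$threshold)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
})
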