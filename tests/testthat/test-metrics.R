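# Brute-force one-vs-rest aggregation: an explicit double loop over
# (sample, class) pairs, independent of the package's vectorized path.
brute_force_counts <- function(truth, scores, mode) {
  classes <- colnames(scores)
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    pred_argmax <- classes[which.max(scores[i, ])]
    for (cl in classes) {
      positive <- truth[i] == cl
      predicted <- if (mode == "argmax") pred_argmax == cl
                   else scores[i, cl] > 0.5
      if (positive && predicted) tp <- tp + 1
      if (positive && !predicted) fn <- fn + 1
      if (!positive && predicted) fp <- fp + 1
      if (!positive && !predicted) tn <- tn + 1
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

random_prob_rows <- function(n, classes, seed) {
  set.seed(seed)
  scores <- matrix(rexp(n * length(classes)), n)
  scores <- scores / rowSums(scores)
  colnames(scores) <- classes
  list(truth = sample(classes, n, replace = TRUE), scores = scores)
}

test_that("argmax aggregation books perfect and near-perfect predictions", {
  classes <- c("Cyst", "Normal", "Stone", "Tumor")
  n <- 20
  truth <- rep(classes, each = 5)
  scores <- matrix(0.01, n, 4, dimnames = list(NULL, classes))
  scores[cbind(seq_len(n), match(truth, classes))] <- 0.97
  cm <- aggregate_confusion(truth, scores)
  expect_equal(cm$TP, n)
  expect_equal(cm$TN, 3 * n)
  expect_equal(cm$FP, 0)
  expect_equal(cm$FN, 0)

  # one misclassified sample adds exactly one FP and one FN
  scores[1, ] <- c(0.01, 0.97, 0.01, 0.01)
  cm1 <- aggregate_confusion(truth, scores)
  expect_equal(cm1$FP, 1)
  expect_equal(cm1$FN, 1)
  expect_equal(cm1$TP, n - 1)

  expect_error(aggregate_confusion(truth[-1], scores), "differ in length")
})

test_that("aggregation agrees with the brute-force double loop", {
  for (seed in 1:6) {
    inst <- random_prob_rows(50, paste("Grade", 0:4), seed)
    for (mode in c("argmax", "threshold")) {
      got <- aggregate_confusion(inst$truth, inst$scores, mode)
      want <- brute_force_counts(inst$truth, inst$scores, mode)
      expect_equal(got[c("TP", "TN", "FP", "FN")], want)
    }
    # pooled argmax counts always balance FP against FN
    cm <- aggregate_confusion(inst$truth, inst$scores, "argmax")
    expect_equal(cm$FP, cm$FN)
    expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, 50 * 5)
  }
})

test_that("closed-form metrics reproduce the published confusion rows", {
  # four-class rows
  vgg16 <- compute_metrics(confusion_counts(19920, 60578, 334, 384))
  expect_equal(percent(vgg16$sensitivity), 98.11)
  expect_equal(percent(vgg16$precision), 98.35)
  expect_equal(percent(vgg16$specificity), 99.45)

  dense4 <- compute_metrics(confusion_counts(20300, 60910, 2, 4))
  expect_equal(percent(dense4$sensitivity), 99.98)
  expect_equal(percent(dense4$precision), 99.99)
  expect_equal(percent(dense4$specificity), 100)

  mobile4 <- compute_metrics(confusion_counts(20300, 60908, 4, 4))
  expect_equal(percent(mobile4$sensitivity), 99.98)
  expect_equal(percent(mobile4$precision), 99.98)
  expect_equal(percent(mobile4$specificity), 99.99)

  # five-class rows
  dense5 <- compute_metrics(confusion_counts(320, 1280, 0, 0))
  expect_equal(percent(dense5$precision), 100)
  expect_equal(percent(dense5$sensitivity), 100)
  expect_equal(percent(dense5$specificity), 100)

  xcep5 <- compute_metrics(confusion_counts(312, 1248, 0, 0))
  expect_equal(percent(xcep5$sensitivity), 100)

  mobile5 <- compute_metrics(confusion_counts(323, 1308, 4, 5))
  expect_equal(percent(mobile5$sensitivity), 98.48)
  expect_equal(percent(mobile5$precision), 98.78)
  expect_equal(percent(mobile5$specificity), 99.70)
})

test_that("degenerate denominators give absent metrics, and F1 is bounded", {
  sym <- compute_metrics(confusion_counts(1, 1, 1, 1))
  expect_equal(percent(sym$precision), 50)
  expect_equal(percent(sym$sensitivity), 50)
  expect_equal(percent(sym$specificity), 50)
  expect_equal(percent(sym$f1), 50)

  none <- compute_metrics(confusion_counts(0, 5, 0, 0))
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$precision))
  expect_equal(none$specificity, 1)

  set.seed(8)
  for (i in 1:50) {
    cm <- confusion_counts(sample(1:500, 1), sample(1:500, 1),
                           sample(1:100, 1), sample(1:100, 1))
    m <- compute_metrics(cm)
    expect_gte(m$f1, 0)
    expect_lte(m$f1, (m$precision + m$sensitivity) / 2 + 1e-12)
  }
})

test_that("rank and overlap metrics have the right closed forms", {
  classes <- c("a", "b", "c")
  truth <- c("a", "b", "c", "a")
  perfect <- matrix(0.005, 4, 3, dimnames = list(NULL, classes))
  perfect[cbind(1:4, match(truth, classes))] <- 0.99
  cur <- compute_curve_metrics(truth, perfect)
  expect_equal(cur$auc, 1)
  expect_equal(cur$iou, 1)
  expect_equal(cur$cosine_similarity, 0.99 / sqrt(0.99^2 + 2 * 0.005^2))

  uniform <- matrix(1 / 3, 4, 3, dimnames = list(NULL, classes))
  expect_equal(compute_curve_metrics(truth, uniform)$cosine_similarity,
               1 / sqrt(3))

  # single-class truth: AUC absent
  one <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, byrow = TRUE,
                dimnames = list(NULL, c("a", "b")))
  expect_true(is.na(compute_curve_metrics(c("a", "a"), one)$auc))
})

test_that("macro AUC agrees with the O(n^2) pairwise oracle", {
  pairwise_auc <- function(truth, scores) {
    classes <- colnames(scores)
    aucs <- c()
    for (cl in classes) {
      pos <- which(truth == cl)
      neg <- which(truth != cl)
      if (!length(pos) || !length(neg)) next
      wins <- 0
      for (i in pos) for (j in neg) {
        if (scores[i, cl] > scores[j, cl]) wins <- wins + 1
        else if (scores[i, cl] == scores[j, cl]) wins <- wins + 0.5
      }
      aucs <- c(aucs, wins / (length(pos) * length(neg)))
    }
    mean(aucs)
  }
  for (seed in 1:4) {
    inst <- random_prob_rows(30, c("x", "y", "z"), 100 + seed)
    expect_equal(compute_curve_metrics(inst$truth, inst$scores)$auc,
                 pairwise_auc(inst$truth, inst$scores), tolerance = 1e-12)
  }
})

test_that("metric_report assembles counts and percentages consistently", {
  inst <- random_prob_rows(40, c("p", "q"), 77)
  rep <- metric_report(inst$truth, inst$scores)
  cm <- aggregate_confusion(inst$truth, inst$scores)
  expect_equal(rep$counts$TP, cm$TP)
  expect_equal(rep$accuracy,
               (cm$TP + cm$TN) / (cm$TP + cm$TN + cm$FP + cm$FN))
  df <- as.data.frame(rep)
  expect_identical(names(df)[1:2], c("accuracy", "f1"))
  expect_equal(df$accuracy, percent(rep$accuracy))
})

test_that("percentage display rounds half away from zero at 2 decimals", {
  expect_equal(percent(0.98345), 98.35)  # base round() would give 98.34
  expect_equal(percent(0.5), 50)
  expect_true(is.na(percent(NA_real_)))
})
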