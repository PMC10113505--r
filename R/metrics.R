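# One-vs-rest multiclass confusion aggregation and the closed-form metric
# suite.  Counts are pooled over every (sample, class) pair, so for C classes
# and n samples TP + TN + FP + FN = C * n under argmax prediction.

#' Aggregate one-vs-rest confusion counts
#'
#' Each sample contributes one binary outcome per class: the class is the
#' "positive" label iff it equals the true label, and is "predicted" either
#' because it wins the argmax over the probability row (\code{mode =
#' "argmax"}, exactly one prediction per sample) or because its probability
#' exceeds 0.5 (\code{mode = "threshold"}, zero or several predictions per
#' sample).  Counts are summed over all classes.
#'
#' @param true_labels vector (factor/character/integer) of true classes.
#' @param predicted_scores numeric matrix, one row per sample, one column per
#'   class; column names (or factor levels) identify the classes.
#' @param mode \code{"argmax"} or \code{"threshold"}.
#' @return a \code{confusion_counts} object: list with \code{TP}, \code{TN},
#'   \code{FP}, \code{FN}, \code{n_samples}, \code{n_classes}, \code{mode}.
#' @examples
#' p <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
#'             dimnames = list(NULL, c("a", "b")))
#' aggregate_confusion(c("a", "b"), p)
#' @export
aggregate_confusion <- function(true_labels, predicted_scores,
                                mode = c("argmax", "threshold")) {
  mode <- match.arg(mode)
  scores <- as.matrix(predicted_scores)
  n <- nrow(scores)
  if (length(true_labels) != n) {
    stop_invalid("true_labels (", length(true_labels),
                 ") and predicted_scores rows (", n, ") differ in length")
  }
  classes <- colnames(scores) %||% as.character(seq_len(ncol(scores)))
  truth <- as.character(true_labels)
  if (!all(truth %in% classes)) {
    stop_invalid("some true labels are not score columns: ",
                 paste(setdiff(unique(truth), classes), collapse = ", "))
  }
  pred <- if (mode == "argmax") {
    # one predicted class per sample; ties broken by first column
    idx <- max.col(scores, ties.method = "first")
    outer(seq_len(n), seq_along(classes),
          function(i, j) idx[i] == j)
  } else {
    scores > 0.5
  }
  pos <- outer(truth, classes, `==`)
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos)
  confusion_counts(tp, tn, fp, fn, n_samples = n,
                   n_classes = length(classes), mode = mode)
}

#' @rdname aggregate_confusion
#' @param TP,TN,FP,FN non-negative integer counts.
#' @param n_samples,n_classes optional bookkeeping.
#' @export
confusion_counts <- function(TP, TN, FP, FN, n_samples = NA_integer_,
                             n_classes = NA_integer_, mode = NA_character_) {
  for (v in list(TP, TN, FP, FN)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop_invalid("confusion counts must be non-negative numbers")
    }
  }
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, n_samples = n_samples,
                 n_classes = n_classes, mode = mode),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%s TN=%s FP=%s FN=%s (%s)\n",
              x$TP, x$TN, x$FP, x$FN,
              if (is.na(x$mode)) "mode unknown" else x$mode))
  invisible(x)
}

#' Closed-form metrics from pooled confusion counts
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), sensitivity
#' (recall) TP/(TP+FN), specificity TN/(TN+FP), and F1 =
#' 2TP/(2TP+FP+FN).  A metric whose denominator is zero is reported as
#' \code{NA} (absent), never as 0.  Values are fractions; use [percent()]
#' for the 2-decimal half-up display convention.
#'
#' @param cm a [confusion_counts()] object.
#' @return named list of fractions (possibly NA).
#' @examples
#' m <- compute_metrics(confusion_counts(19920, 60578, 334, 384))
#' percent(m$sensitivity) # 98.11
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  with(cm, list(
    accuracy = frac(TP + TN, TP + TN + FP + FN),
    precision = frac(TP, TP + FP),
    sensitivity = frac(TP, TP + FN),
    specificity = frac(TN, TN + FP),
    f1 = frac(2 * TP, 2 * TP + FP + FN)
  ))
}

#' Rank/overlap metrics from probability rows
#'
#' AUC is the macro average over classes of the one-vs-rest rank statistic
#' (Mann-Whitney with mid-ranks for ties); classes without both a positive
#' and a negative sample are skipped, and AUC is \code{NA} if no class
#' qualifies.  IoU is TP/(TP+FP+FN) from the argmax-pooled counts.  Cosine
#' similarity is the mean over samples of the cosine between the one-hot
#' truth and the probability row.
#'
#' @inheritParams aggregate_confusion
#' @return list with \code{auc}, \code{iou}, \code{cosine_similarity}
#'   (fractions).
#' @export
compute_curve_metrics <- function(true_labels, predicted_scores) {
  scores <- as.matrix(predicted_scores)
  classes <- colnames(scores) %||% as.character(seq_len(ncol(scores)))
  truth <- as.character(true_labels)
  if (length(truth) != nrow(scores)) stop_invalid("length mismatch")

  aucs <- vapply(seq_along(classes), function(j) {
    pos <- truth == classes[j]
    npos <- sum(pos); nneg <- sum(!pos)
    if (npos == 0 || nneg == 0) return(NA_real_)
    r <- rank(scores[, j])
    (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  }, numeric(1))
  auc <- if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)

  cm <- aggregate_confusion(true_labels, scores, mode = "argmax")
  iou <- if (cm$TP + cm$FP + cm$FN > 0) cm$TP / (cm$TP + cm$FP + cm$FN)
         else NA_real_

  norms <- sqrt(rowSums(scores^2))
  p_true <- scores[cbind(seq_along(truth), match(truth, classes))]
  cosine <- mean(ifelse(norms > 0, p_true / norms, 0))

  list(auc = auc, iou = iou, cosine_similarity = cosine)
}

#' Full metric report for a set of predictions
#'
#' Combines the pooled confusion counts, the closed-form metrics, and the
#' rank/overlap metrics into one record.
#'
#' @inheritParams aggregate_confusion
#' @return a \code{metric_report}: list with \code{counts} and the metric
#'   fields as fractions.
#' @export
metric_report <- function(true_labels, predicted_scores,
                          mode = c("argmax", "threshold")) {
  mode <- match.arg(mode)
  cm <- aggregate_confusion(true_labels, predicted_scores, mode)
  closed <- compute_metrics(cm)
  curve <- compute_curve_metrics(true_labels, predicted_scores)
  structure(c(list(counts = cm), closed, curve), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  print(x$counts)
  fields <- c("accuracy", "f1", "precision", "sensitivity", "specificity",
              "auc", "iou", "cosine_similarity")
  for (f in fields) {
    v <- x[[f]]
    cat(sprintf("  %-18s %s\n", f,
                if (is.na(v)) "NA" else sprintf("%.2f%%", percent(v))))
  }
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(
    accuracy = percent(x$accuracy), f1 = percent(x$f1),
    precision = percent(x$precision), sensitivity = percent(x$sensitivity),
    specificity = percent(x$specificity), auc = percent(x$auc),
    iou = percent(x$iou), cosine_similarity = percent(x$cosine_similarity)
  )
}
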