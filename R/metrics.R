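#' Confusion matrix of predicted vs true labels
#'
#' @param truth Vector of true labels.
#' @param estimate Vector of predicted labels (same length).
#' @param levels Optional explicit class levels; defaults to the union of
#'   levels found in `truth` and `estimate`.
#' @return A K x K integer matrix of class `confusion_matrix` with true
#'   classes in rows and predicted classes in columns.
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
confusion_matrix <- function(truth, estimate, levels = NULL) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length")
  }
  if (length(truth) == 0) abort("cannot build a confusion matrix from 0 frames")
  if (is.null(levels)) {
    levels <- union(levels(factor(truth)), levels(factor(estimate)))
  }
  t_f <- factor(truth, levels = levels)
  e_f <- factor(estimate, levels = levels)
  m <- table(truth = t_f, predicted = e_f)
  structure(unclass(m), class = c("confusion_matrix", "matrix"))
}

#' Binary confusion matrix from TP/TN/FP/FN counts
#'
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @return A 2 x 2 `confusion_matrix` with classes `0` (negative) and `1`
#'   (positive).
#' @export
#' @examples
#' accuracy(binary_confusion(tp = 45, tn = 40, fp = 5, fn = 10))
binary_confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("tp, tn, fp, fn must be nonnegative integers")
  }
  m <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Classification accuracy
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN); for multi-class matrices the
#' generalisation trace / total.
#'
#' @param x A `confusion_matrix`, or a vector of true labels when `estimate`
#'   is supplied.
#' @param estimate Optional predicted labels.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' accuracy(binary_confusion(10, 10, 0, 0))
accuracy <- function(x, estimate = NULL) {
  cm <- if (inherits(x, "confusion_matrix")) x else confusion_matrix(x, estimate)
  n <- sum(cm)
  if (n < 1) abort("empty confusion matrix")
  sum(diag(cm)) / n
}

.check_pairs <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("ground-truth and predicted vectors must have equal length")
  }
  if (length(truth) < 1) abort("need at least one observation")
}

#' Mean absolute percentage error (MAPE)
#'
#' `MAPE(%) = (100 / n) * sum(|Y_i - X_i| / Y_i)` where `Y_i` is the ground
#' truth and `X_i` the prediction. Reported on the 0--100 scale.
#'
#' @param truth Ground-truth values (all strictly positive).
#' @param estimate Predicted values.
#' @return MAPE in percent.
#' @export
#' @examples
#' mape(c(200, 400), c(220, 380))  # 7.5
mape <- function(truth, estimate) {
  .check_pairs(truth, estimate)
  if (any(truth <= 0)) {
    abort("MAPE is undefined for ground-truth values <= 0")
  }
  100 / length(truth) * sum(abs(truth - estimate) / truth)
}

#' Mean absolute error (MAE)
#'
#' `MAE = (1 / n) * sum(|Y_i - X_i|)`, in the units of the inputs (um for
#' needle-to-dura distances).
#'
#' @inheritParams mape
#' @return MAE in input units.
#' @export
#' @examples
#' mae(c(200, 400), c(220, 380))  # 20
mae <- function(truth, estimate) {
  .check_pairs(truth, estimate)
  mean(abs(truth - estimate))
}

#' ROC curve and area under the curve
#'
#' AUC equals the probability that a randomly chosen positive instance
#' outscores a randomly chosen negative one, ties counted one half. The full
#' ROC point list (sensitivity vs specificity) is returned alongside.
#'
#' @param scores Numeric class-1 scores or probabilities.
#' @param truth Binary labels (0/1, logical, or two-level factor); class 1
#'   is the positive (deeper-tissue) class.
#' @return A list with `auc` (scalar) and `roc`, a tibble with columns
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0))$auc  # 1
roc_auc <- function(scores, truth) {
  .check_pairs(truth, scores)
  y <- as.integer(as.factor(truth)) - 1L
  if (length(unique(y)) < 2) {
    abort("both classes must be present to compute a ROC curve")
  }
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  list(
    auc = as.numeric(pROC::auc(r)),
    roc = tibble(threshold = r$thresholds,
                 sensitivity = r$sensitivities,
                 specificity = r$specificities)
  )
}

#' Aggregate per-fold metrics as mean and standard error
#'
#' The standard error is the sample (n - 1) standard deviation divided by
#' sqrt(number of folds). A single fold yields SE 0, flagged via
#' `se_degenerate`.
#'
#' @param values Numeric vector of per-fold metric values.
#' @return One-row tibble with `n`, `mean`, `se`, `se_degenerate`.
#' @export
#' @examples
#' aggregate_mean_se(c(90, 94))  # mean 92, se 2
aggregate_mean_se <- function(values) {
  if (length(values) == 0) abort("cannot aggregate an empty metric list")
  n <- length(values)
  se <- if (n == 1) 0 else sd(values) / sqrt(n)
  tibble(n = n, mean = mean(values), se = se, se_degenerate = n == 1)
}
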