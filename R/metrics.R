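#' Binary classification metrics
#'
#' Confusion-matrix metrics used throughout the pipeline. `mcc()` is the
#' Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0 when
#' any marginal is empty. `balanced_accuracy()` is (sensitivity +
#' specificity) / 2. `auc_score()` is the area under the ROC curve computed
#' exactly via the Mann-Whitney rank statistic (ties contribute 1/2).
#'
#' @param y_true binary vector (0/1 or logical) of true labels.
#' @param y_pred binary vector of predicted labels.
#' @param scores numeric score/probability vector, higher = more positive.
#' @return a numeric scalar.
#' @export
mcc <- function(y_true, y_pred) {
  cm <- confusion_counts(y_true, y_pred)
  # one sqrt of the exact integer product: factored square roots can push
  # a rational value like 1/2 off by an ulp, which matters at strict gates
  denom <- sqrt((cm$tp + cm$fp) * (cm$tp + cm$fn) *
                  (cm$tn + cm$fp) * (cm$tn + cm$fn))
  if (denom == 0) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / denom
}

#' @rdname mcc
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  cm <- confusion_counts(y_true, y_pred)
  tpr <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
  tnr <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else 0
  (tpr + tnr) / 2
}

#' @rdname mcc
#' @export
auc_score <- function(y_true, scores) {
  y <- as_binary(y_true)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname mcc
#' @return `confusion_counts()` returns a list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y <- as_binary(y_true)
  p <- as_binary(y_pred)
  stopifnot(length(y) == length(p))
  list(tp = sum(y == 1L & p == 1L), fp = sum(y == 0L & p == 1L),
       tn = sum(y == 0L & p == 0L), fn = sum(y == 1L & p == 0L))
}

as_binary <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    u <- sort(unique(y))
    if (length(u) > 2L) stop("more than two classes", call. = FALSE)
    return(as.integer(y == u[length(u)]))
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)
  y
}

#' Youden-J optimal classification threshold
#'
#' Evaluates Youden's J statistic, J = TPR - FPR, at every distinct observed
#' score treated as the rule "predict positive if score >= t", and returns
#' the maximising threshold. Ties in J are broken towards the smallest
#' threshold, which maximises sensitivity at the optimum.
#'
#' @param y_true binary labels (both classes must be present).
#' @param scores numeric scores aligned with `y_true`.
#' @return a `threshold_result` list: `threshold` (one of the distinct
#'   scores) and `j_value` (the maximal J, in \[0, 1\] for any non-trivial
#'   scorer).
#' @export
youden_threshold <- function(y_true, scores) {
  y <- as_binary(y_true)
  if (length(unique(y)) < 2L) {
    stop("both classes required to choose a threshold", call. = FALSE)
  }
  cand <- sort(unique(scores))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & y == 1L) / n1 - sum(pred & y == 0L) / n0
  }, numeric(1L))
  best <- which(j == max(j))[1L]  # cand is sorted: first max = smallest t
  structure(list(threshold = cand[best], j_value = j[best]),
            class = "threshold_result")
}
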