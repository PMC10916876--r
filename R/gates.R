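#' Quality gates for candidate feature subsets
#'
#' Two baseline-model gates decide which (readout, feature subset) and
#' (readout, perturbation group) combinations carry enough signal to become
#' terms. [gate_readout_regression()] fits ordinary least squares on a
#' random 80/20 train-test split and passes when the test-set R-squared
#' exceeds 0.25. [gate_group_classifier()] fits a baseline random forest on
#' a stratified 80/20 split of negative controls vs one perturbation group
#' and passes when the test-set Matthews correlation coefficient (at the 0.5
#' probability cut) exceeds 0.50.
#'
#' @param X_subset numeric matrix restricted to the candidate feature subset
#'   (may have zero columns: the gate then fails with value `-Inf`).
#' @param y_readout continuous readout vector aligned with rows.
#' @param split_seed integer seed controlling the train-test split (and the
#'   forest, for the classifier gate).
#' @param threshold pass threshold; strict inequality is applied.
#' @return a `gate_result` list: `metric_name`, `value`, `passed`,
#'   `split_seed`, `threshold`.
#' @export
gate_readout_regression <- function(X_subset, y_readout, split_seed,
                                    threshold = 0.25) {
  X_subset <- as.matrix(X_subset)
  if (ncol(X_subset) == 0L) {
    return(gate_result("r_squared", -Inf, split_seed, threshold))
  }
  n <- nrow(X_subset)
  if (n < 10L) stop("need >= 10 rows for the regression gate", call. = FALSE)
  idx <- with_preserved_rng({
    set.seed(derive_seed(split_seed, 1L))
    sample.int(n)
  })
  n_test <- max(1L, round(0.2 * n))
  test <- idx[seq_len(n_test)]
  train <- idx[-seq_len(n_test)]
  df <- as.data.frame(X_subset)
  names(df) <- paste0("x", seq_len(ncol(df)))  # guard non-syntactic names
  df$.y <- y_readout
  fit <- stats::lm(.y ~ ., data = df[train, , drop = FALSE])
  pred <- stats::predict(fit, newdata = df[test, , drop = FALSE])
  pred[!is.finite(pred)] <- mean(y_readout[train])
  r2 <- 1 - sum((y_readout[test] - pred)^2) /
    sum((y_readout[test] - mean(y_readout[test]))^2)
  gate_result("r_squared", r2, split_seed, threshold)
}

#' @rdname gate_readout_regression
#' @param control_mask logical vector: `TRUE` = negative control; the gate
#'   classifies controls against group members.
#' @param num_trees forest size of the baseline classifier.
#' @export
gate_group_classifier <- function(X_subset, control_mask, split_seed,
                                  threshold = 0.50, num_trees = 100L) {
  X_subset <- as.matrix(X_subset)
  if (ncol(X_subset) && is.null(colnames(X_subset))) {
    colnames(X_subset) <- paste0("V", seq_len(ncol(X_subset)))
  }
  y <- factor(ifelse(control_mask, "control", "group"),
              levels = c("control", "group"))
  if (ncol(X_subset) == 0L || length(unique(y)) < 2L) {
    return(gate_result("mcc", -Inf, split_seed, threshold))
  }
  split <- stratified_split(y, test_frac = 0.2,
                            seed = derive_seed(split_seed, 2L))
  if (length(unique(y[split$train])) < 2L ||
      length(unique(y[split$test])) < 2L) {
    return(gate_result("mcc", -Inf, split_seed, threshold))
  }
  fit <- ranger::ranger(x = X_subset[split$train, , drop = FALSE],
                        y = y[split$train],
                        num.trees = num_trees, probability = TRUE,
                        num.threads = 1L,
                        seed = derive_seed(split_seed, 3L))
  prob <- stats::predict(fit, X_subset[split$test, , drop = FALSE],
                         num.threads = 1L)$predictions[, "group"]
  value <- mcc(y[split$test] == "group", prob >= 0.5)
  gate_result("mcc", value, split_seed, threshold)
}

# the pass rule lives here so the strict inequality is applied uniformly:
# a gate value exactly at the threshold does NOT pass
gate_result <- function(metric_name, value, split_seed, threshold) {
  structure(list(metric_name = metric_name, value = value,
                 passed = is.finite(value) && value > threshold,
                 split_seed = as.integer(split_seed),
                 threshold = threshold),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate %s = %.4f (> %.2f: %s)\n", x$metric_name, x$value,
              x$threshold, if (x$passed) "passed" else "failed"))
  invisible(x)
}

# stratified holdout: within each class, a seeded shuffle then the first
# test_frac of rows (>= 1 per class) go to the test set
stratified_split <- function(y, test_frac, seed) {
  test <- integer(0)
  with_preserved_rng({
    set.seed(seed)
    for (cl in levels(factor(y))) {
      rows <- which(y == cl)
      rows <- rows[sample.int(length(rows))]
      n_test <- max(1L, round(test_frac * length(rows)))
      test <- c(test, rows[seq_len(n_test)])
    }
  })
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

# stratified k-fold assignment: seeded shuffle within class, round-robin
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_preserved_rng({
    set.seed(seed)
    for (cl in levels(factor(y))) {
      rows <- which(y == cl)
      rows <- rows[sample.int(length(rows))]
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}
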