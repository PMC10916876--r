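#' Cross-validation configuration for activity models
#'
#' Defaults follow the evaluation protocol used throughout: five times
#' repeated stratified fourfold outer cross-validation (20 test sets), an
#' inner fivefold stratified successive-halving random search, and
#' Youden-J threshold selection from inner cross-validation predictions.
#'
#' The search samples `n_candidates` hyperparameter combinations from the
#' declared grid (max depth 5/10/20/unlimited, max features sqrt/log2/0.3,
#' min samples per leaf 1/3/5). The halving resource is the number of trees
#' (rungs 25, 75, 225; the top third survives each rung); the winner is
#' refit with `final_trees` trees.
#'
#' @param n_repeats,n_outer_folds,inner_folds protocol sizes.
#' @param n_candidates hyperparameter combinations sampled per search.
#' @param rung_trees tree budgets of the successive-halving rungs.
#' @param halving_factor fraction of candidates kept per rung is
#'   1/halving_factor.
#' @param final_trees forest size of the refit winner.
#' @param threshold_rule only `"youden"` is implemented.
#' @param seed integer master seed for splits, search and fits.
#' @return a `cv_config` list.
#' @export
cv_config <- function(n_repeats = 5L, n_outer_folds = 4L, inner_folds = 5L,
                      n_candidates = 8L, rung_trees = c(25L, 75L, 225L),
                      halving_factor = 3, final_trees = 500L,
                      threshold_rule = "youden", seed = 1L) {
  stopifnot(n_repeats >= 1L, n_outer_folds >= 2L, inner_folds >= 2L,
            n_candidates >= 1L, all(rung_trees >= 1L), halving_factor > 1,
            identical(threshold_rule, "youden"))
  structure(list(n_repeats = as.integer(n_repeats),
                 n_outer_folds = as.integer(n_outer_folds),
                 inner_folds = as.integer(inner_folds),
                 n_candidates = as.integer(n_candidates),
                 rung_trees = as.integer(rung_trees),
                 halving_factor = halving_factor,
                 final_trees = as.integer(final_trees),
                 threshold_rule = threshold_rule,
                 seed = as.integer(seed)),
            class = "cv_config")
}

# declared hyperparameter grid; max.depth 0 = unlimited in ranger
rf_grid <- function() {
  expand.grid(max_depth = c(5L, 10L, 20L, 0L),
              max_features = c("sqrt", "log2", "0.3"),
              min_node = c(1L, 3L, 5L),
              stringsAsFactors = FALSE)
}

resolve_mtry <- function(rule, p) {
  m <- switch(rule,
              sqrt = floor(sqrt(p)),
              log2 = floor(log2(p)),
              `0.3` = floor(0.3 * p))
  max(1L, min(p, as.integer(m)))
}

fit_rf <- function(X, y, params, num_trees, seed) {
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  ranger::ranger(x = X, y = factor(y, levels = c(0L, 1L)),
                 num.trees = num_trees,
                 max.depth = params$max_depth,
                 mtry = resolve_mtry(params$max_features, ncol(X)),
                 min.node.size = params$min_node,
                 probability = TRUE, importance = "impurity",
                 num.threads = 1L, seed = seed)
}

predict_rf <- function(fit, X) {
  stats::predict(fit, as.matrix(X), num.threads = 1L)$predictions[, "1"]
}

# out-of-fold probabilities from a stratified k-fold fit of one config
cv_scores <- function(X, y, params, num_trees, k, seed) {
  fold <- stratified_folds(factor(y), k, seed)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_rf(X[tr, , drop = FALSE], y[tr], params, num_trees,
                  seed = derive_seed(seed, f))
    scores[!tr] <- predict_rf(fit, X[!tr, , drop = FALSE])
  }
  scores
}

# successive-halving random search maximising inner-CV AUC
halving_search <- function(X, y, config, seed) {
  grid <- rf_grid()
  n_cand <- min(config$n_candidates, nrow(grid))
  idx <- with_preserved_rng({
    set.seed(derive_seed(seed, 7L))
    sample.int(nrow(grid), n_cand)
  })
  cand <- grid[idx, , drop = FALSE]
  for (r in seq_along(config$rung_trees)) {
    auc <- vapply(seq_len(nrow(cand)), function(i) {
      sc <- cv_scores(X, y, cand[i, ], config$rung_trees[r],
                      config$inner_folds, seed = derive_seed(seed, 50L + i))
      auc_score(y, sc)
    }, numeric(1L))
    keep <- order(-auc, seq_len(nrow(cand)))  # ties: earlier candidate wins
    n_keep <- max(1L, ceiling(nrow(cand) / config$halving_factor))
    cand <- cand[keep[seq_len(n_keep)], , drop = FALSE]
    if (nrow(cand) == 1L) break
  }
  cand[1L, , drop = FALSE]
}

check_classes <- function(y, min_per_class = 8L) {
  tab <- table(as_binary(y))
  if (length(tab) < 2L || any(tab < min_per_class)) {
    stop("need >= ", min_per_class, " samples in each class", call. = FALSE)
  }
}

#' Repeated nested cross-validated evaluation
#'
#' The outer loop is a stratified `n_outer_folds`-fold split repeated
#' `n_repeats` times (20 test sets under the defaults). On each outer
#' training split a successive-halving random search with stratified
#' `inner_folds`-fold cross-validation picks the forest hyperparameters
#' (optimising inner AUC); the winner is refit on the whole outer training
#' split, the classification threshold is chosen by Youden's J on inner
#' cross-validation predictions, and AUC, balanced accuracy and MCC are
#' recorded on the outer test split.
#'
#' @param X numeric matrix (profiles x features or profiles x terms).
#' @param y binary activity labels (>= 8 per class).
#' @param config a [cv_config()].
#' @return an `eval_report`: data.frame with one row per (repeat, fold)
#'   containing metrics, the chosen threshold and hyperparameters, and the
#'   test-set confusion counts; the config is attached as an attribute.
#' @export
nested_cv_evaluate <- function(X, y, config = cv_config()) {
  X <- as.matrix(X)
  y <- as_binary(y)
  check_classes(y)
  if (min(table(y)) < config$n_outer_folds) {
    stop("stratified ", config$n_outer_folds, "-fold split impossible: ",
         "minority class too small", call. = FALSE)
  }
  rows <- list()
  for (rep in seq_len(config$n_repeats)) {
    fold <- stratified_folds(factor(y), config$n_outer_folds,
                             seed = derive_seed(config$seed, 1000L + rep))
    for (f in seq_len(config$n_outer_folds)) {
      te <- fold == f
      rec <- fit_and_score_split(X[!te, , drop = FALSE], y[!te],
                                 X[te, , drop = FALSE], y[te], config,
                                 seed = derive_seed(config$seed,
                                                    10000L * rep + f))
      rec$rep <- rep
      rec$fold <- f
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("rep", "fold",
                 setdiff(names(out), c("rep", "fold")))]
  attr(out, "config") <- config
  class(out) <- c("eval_report", "data.frame")
  out
}

# shared by nested CV and the held-out protocol: tune, threshold, refit,
# score one train/test split; returns a one-row data.frame (+ model)
fit_and_score_split <- function(X_tr, y_tr, X_te, y_te, config, seed,
                                return_model = FALSE) {
  best <- halving_search(X_tr, y_tr, config, seed = derive_seed(seed, 1L))
  thr_scores <- cv_scores(X_tr, y_tr, best, config$final_trees,
                          config$inner_folds, seed = derive_seed(seed, 2L))
  thr <- youden_threshold(y_tr, thr_scores)
  model <- fit_rf(X_tr, y_tr, best, config$final_trees,
                  seed = derive_seed(seed, 3L))
  prob <- predict_rf(model, X_te)
  pred <- as.integer(prob >= thr$threshold)
  cm <- confusion_counts(y_te, pred)
  rec <- data.frame(auc = auc_score(y_te, prob),
                    balanced_accuracy = balanced_accuracy(y_te, pred),
                    mcc = mcc(y_te, pred),
                    threshold = thr$threshold, j_value = thr$j_value,
                    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                    max_depth = best$max_depth,
                    max_features = best$max_features,
                    min_node = best$min_node)
  if (return_model) list(record = rec, model = model, threshold = thr,
                         params = best) else rec
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: %d test sets | mean AUC %.3f | mean balanced acc %.3f | mean MCC %.3f\n",
    nrow(x), mean(x$auc), mean(x$balanced_accuracy), mean(x$mcc)))
  invisible(x)
}

#' Train with a fixed held-out test set
#'
#' Splits the data 75/25 with stratification, runs the halving search and
#' Youden-J thresholding on the 75% training part (as in
#' [nested_cv_evaluate()]) and reports final metrics on the untouched 25%.
#' The fitted forest, its training data and the threshold are kept in the
#' returned object so per-compound attributions can be computed later.
#'
#' @param X numeric matrix; `y` binary labels (>= 8 per class).
#' @param y binary activity labels.
#' @param seed integer seed.
#' @param config a [cv_config()] (its `seed` field is ignored in favour of
#'   `seed`).
#' @return a `heldout_fit`: list with `model` (ranger forest), `params`,
#'   `threshold` (`threshold_result`), `report` (one-row `eval_report` for
#'   the held-out set), `train_idx`, `test_idx`, `X_train`, `y_train`,
#'   `X_test`, `y_test`, `scores_test`.
#' @export
train_heldout <- function(X, y, seed = 1L, config = cv_config()) {
  X <- as.matrix(X)
  y <- as_binary(y)
  check_classes(y)
  split <- stratified_split(factor(y), test_frac = 0.25,
                            seed = derive_seed(seed, 11L))
  res <- fit_and_score_split(X[split$train, , drop = FALSE], y[split$train],
                             X[split$test, , drop = FALSE], y[split$test],
                             config, seed = derive_seed(seed, 12L),
                             return_model = TRUE)
  rec <- res$record
  attr(rec, "config") <- config
  class(rec) <- c("eval_report", "data.frame")
  prob_test <- predict_rf(res$model, X[split$test, , drop = FALSE])
  structure(list(model = res$model, params = res$params,
                 threshold = res$threshold, report = rec,
                 train_idx = split$train, test_idx = split$test,
                 X_train = X[split$train, , drop = FALSE],
                 y_train = y[split$train],
                 X_test = X[split$test, , drop = FALSE],
                 y_test = y[split$test],
                 scores_test = prob_test,
                 seed = as.integer(seed)),
            class = "heldout_fit")
}

#' @export
print.heldout_fit <- function(x, ...) {
  cat(sprintf(
    "heldout_fit: %d train / %d test | AUC %.3f | MCC %.3f | threshold %.3f\n",
    length(x$train_idx), length(x$test_idx), x$report$auc, x$report$mcc,
    x$threshold$threshold))
  invisible(x)
}

#' @export
predict.heldout_fit <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  prob <- predict_rf(object$model, as.matrix(newdata))
  if (type == "prob") prob else
    as.integer(prob >= object$threshold$threshold)
}
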