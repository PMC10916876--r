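#' Configuration for all-relevant feature selection
#'
#' @param max_iter maximum number of shadow-competition iterations (>= 1).
#' @param alpha significance level of the binomial decision test, in (0, 1).
#' @param estimator_max_depth maximum tree depth of the forest estimator;
#'   the gene-perturbation pipeline uses depth 5.
#' @param estimator_trees `"auto"` (10 x ceiling(sqrt(number of design
#'   columns)), clipped to \[64, 512\]) or a fixed integer.
#' @param task `"regression"` or `"classification"`.
#' @param seed integer master seed; one child stream per iteration is derived
#'   from it, so runs are exactly reproducible.
#' @return a `selection_config` list.
#' @export
selection_config <- function(max_iter = 100L, alpha = 0.05,
                             estimator_max_depth = 5L,
                             estimator_trees = "auto",
                             task = c("regression", "classification"),
                             seed = 1L) {
  task <- match.arg(task)
  stopifnot(max_iter >= 1L, alpha > 0, alpha < 1, estimator_max_depth >= 1L)
  if (!identical(estimator_trees, "auto")) {
    stopifnot(is.numeric(estimator_trees), estimator_trees >= 1)
  }
  structure(list(max_iter = as.integer(max_iter), alpha = alpha,
                 estimator_max_depth = as.integer(estimator_max_depth),
                 estimator_trees = estimator_trees, task = task,
                 seed = as.integer(seed)),
            class = "selection_config")
}

auto_trees <- function(n_cols) {
  min(512L, max(64L, 10L * as.integer(ceiling(sqrt(n_cols)))))
}

# deterministic child seed; keeps within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' All-relevant feature selection with shadow features
#'
#' Iteratively pits every feature against a "shadow" copy of itself whose
#' values are permuted across rows, destroying any association with the
#' response while preserving the marginal distribution. Each iteration fits
#' a random forest on real + shadow features; a real feature scores a hit
#' when its impurity importance exceeds the maximum importance of all
#' shadows. A two-sided binomial test on accumulated hits (chance level 0.5,
#' Bonferroni-corrected over the features still undecided) confirms features
#' with significantly more hits and rejects features with significantly
#' fewer. Rejected features leave the design; the loop ends when every
#' feature is decided or after `max_iter` iterations, features still
#' undecided being reported as tentative. Unlike minimal-optimal selectors,
#' the procedure aims to keep every feature carrying information about the
#' response, including duplicated ones.
#'
#' @param X a `morph_table` or numeric matrix (>= 10 rows).
#' @param y numeric response (`task = "regression"`) or binary/factor labels
#'   (`task = "classification"`), aligned with the rows of `X`.
#' @param config a [selection_config()].
#' @return a `selection_result`: list with character vectors `confirmed`,
#'   `rejected`, `tentative` (a partition of `colnames(X)`), the integer
#'   matrix `hit_history` (features x iterations; 1 = hit, 0 = no hit,
#'   NA = not tested that iteration), and `n_iter`.
#' @export
all_relevant_select <- function(X, y, config = selection_config()) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (nrow(X) < 10L) stop("need >= 10 rows for selection", call. = FALSE)
  if (length(y) != nrow(X)) stop("y must align with rows of X", call. = FALSE)
  if (length(unique(y)) < 2L) stop("constant response", call. = FALSE)
  if (config$task == "classification") y <- factor(y)

  feats <- colnames(X)
  status <- rep("undecided", p)
  hits <- integer(p)
  trials <- integer(p)
  hist <- matrix(NA_integer_, p, 0L, dimnames = list(feats, NULL))

  with_preserved_rng({
    for (iter in seq_len(config$max_iter)) {
      undecided <- which(status == "undecided")
      if (!length(undecided)) break
      active <- which(status != "rejected")  # confirmed stay in the design
      iter_seed <- derive_seed(config$seed, iter)
      set.seed(iter_seed)
      # pad the shadow pool to at least min(p, 20) columns: the hit bar is
      # the maximum over shadows, so a pool that shrinks with the undecided
      # set would let a lone surviving feature beat a single permutation of
      # itself almost surely; a floored pool keeps the bar calibrated
      shadow_src <- rep_len(active, max(length(active), 20L))
      shadow <- apply(X[, shadow_src, drop = FALSE], 2L,
                      function(col) col[sample.int(length(col))])
      design <- cbind(X[, active, drop = FALSE], shadow)
      colnames(design) <- c(feats[active],
                            paste0(".shadow.", seq_along(shadow_src)))
      n_trees <- if (identical(config$estimator_trees, "auto")) {
        auto_trees(ncol(design))
      } else as.integer(config$estimator_trees)
      fit <- ranger::ranger(
        x = design, y = y,
        num.trees = n_trees,
        max.depth = config$estimator_max_depth,
        importance = "impurity",
        probability = FALSE,
        classification = config$task == "classification",
        num.threads = 1L,
        seed = iter_seed)
      imp <- fit$variable.importance
      shadow_max <- max(imp[grepl("^\\.shadow\\.", names(imp))])
      col <- rep(NA_integer_, p)
      hit <- imp[feats[undecided]] > shadow_max
      col[undecided] <- as.integer(hit)
      hits[undecided] <- hits[undecided] + as.integer(hit)
      trials[undecided] <- trials[undecided] + 1L
      hist <- cbind(hist, col)

      # Bonferroni over all input features and over the sequential test
      # index (the hit tests are repeated every iteration on accumulating
      # counts, so the per-iteration level must shrink); keeping m = p
      # rather than the undecided count stops the level from loosening
      # exactly when survivors are selected for accidental association
      thr <- config$alpha / p / iter
      for (j in undecided) {
        p_more <- stats::pbinom(hits[j] - 1L, trials[j], 0.5,
                                lower.tail = FALSE)
        p_less <- stats::pbinom(hits[j], trials[j], 0.5)
        if (p_more < thr) status[j] <- "confirmed"
        else if (p_less < thr) status[j] <- "rejected"
      }
    }
  })

  colnames(hist) <- paste0("iter", seq_len(ncol(hist)))
  structure(list(confirmed = feats[status == "confirmed"],
                 rejected = feats[status == "rejected"],
                 tentative = feats[status == "undecided"],
                 hit_history = hist,
                 n_iter = ncol(hist),
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("all-relevant selection:", length(x$confirmed), "confirmed,",
      length(x$rejected), "rejected,", length(x$tentative),
      "tentative after", x$n_iter, "iterations\n")
  if (length(x$confirmed)) {
    cat("confirmed:", paste(utils::head(x$confirmed, 10L), collapse = ", "),
        if (length(x$confirmed) > 10L) "..." else "", "\n")
  }
  invisible(x)
}
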