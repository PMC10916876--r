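#' Select the most important features of a model or compound
#'
#' Applies the two-standard-deviation rule: a feature is "important" when
#' its importance (or attribution) strictly exceeds mean + 2 sd of the whole
#' vector. The sd convention defaults to population (divisor n); both the
#' convention and strictness are switchable because reasonable analyses
#' differ here. A constant vector has sd 0 and nothing strictly exceeds its
#' mean, so the selection is empty.
#'
#' @param importances named non-negative numeric vector (model-level
#'   impurity importances) or a signed attribution vector (compound level;
#'   pass `positive_only = TRUE` to restrict to positively contributing
#'   features before thresholding).
#' @param convention `"population"` (divisor n) or `"sample"` (divisor
#'   n - 1) standard deviation.
#' @param strict if `TRUE` (default) the cut is `>`, else `>=`.
#' @param positive_only drop non-positive entries first (used for
#'   per-compound attributions, where positive values push the prediction
#'   towards activity).
#' @param source provenance tag stored in the result.
#' @return an `important_set`: list with `feature_names`, `rule`,
#'   `source` and `threshold_value` (= mean + 2 sd of the vector used).
#' @export
select_important <- function(importances,
                             convention = c("population", "sample"),
                             strict = TRUE, positive_only = FALSE,
                             source = "model_importance") {
  convention <- match.arg(convention)
  v <- importances
  if (positive_only) v <- v[v > 0]
  if (length(v) < 2L) {
    return(structure(list(feature_names = character(0),
                          rule = "mean_plus_2sd", source = source,
                          threshold_value = NA_real_),
                     class = "important_set"))
  }
  mu <- mean(v)
  s <- if (convention == "population") sqrt(mean((v - mu)^2)) else stats::sd(v)
  cut <- mu + 2 * s
  sel <- if (strict) v > cut else v >= cut
  structure(list(feature_names = names(v)[sel], rule = "mean_plus_2sd",
                 source = source, threshold_value = cut),
            class = "important_set")
}

#' @export
print.important_set <- function(x, ...) {
  cat("important_set:", length(x$feature_names), "features (",
      x$rule, ", cut =", format(x$threshold_value, digits = 4), ") from",
      x$source, "\n")
  invisible(x)
}

#' Per-feature additive attributions for single predictions
#'
#' Computes path-based (Saabas-style) attributions over the fitted forest:
#' for every tree, walking the prediction path of a profile, the change in
#' the node's expected positive-class probability at each split is credited
#' to the split feature; node expectations are computed by routing the
#' training data through each tree. Attributions are additive and satisfy
#' local accuracy exactly: for each profile they sum to the forest's
#' predicted probability minus a constant baseline (the mean root
#' expectation over trees), and a feature the forest never splits on
#' receives attribution 0.
#'
#' @param fit a `heldout_fit` (or any list with elements `model` (a ranger
#'   probability forest) and `X_train`).
#' @param x_rows numeric matrix (or single named vector) of profiles in the
#'   model's feature space.
#' @return matrix rows x features of attributions, with attributes
#'   `baseline` (scalar) and `scores` (the forest probabilities; for each
#'   row, `sum(attributions) + baseline == score`).
#' @export
attribute_compound <- function(fit, x_rows) {
  model <- fit$model
  if (is.null(model) || !inherits(model, "ranger")) {
    stop("fit must contain a fitted ranger model", call. = FALSE)
  }
  if (is.null(dim(x_rows))) x_rows <- matrix(x_rows, nrow = 1L,
                                             dimnames = list(NULL, names(x_rows)))
  x_rows <- as.matrix(x_rows)
  feats <- model$forest$independent.variable.names
  missing <- setdiff(feats, colnames(x_rows))
  if (length(missing)) {
    stop("rows lack model features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x_rows <- x_rows[, feats, drop = FALSE]
  X_train <- as.matrix(fit$X_train)[, feats, drop = FALSE]

  m <- nrow(x_rows)
  contrib <- matrix(0, m, length(feats), dimnames = list(rownames(x_rows), feats))
  baseline <- 0
  pos_col <- which(colnames(stats::predict(
    model, X_train[1L, , drop = FALSE], num.threads = 1L)$predictions) == "1")

  for (t in seq_len(model$num.trees)) {
    ti <- ranger::treeInfo(model, t)
    left <- ti$leftChild + 1L
    right <- ti$rightChild + 1L
    svar <- ti$splitvarID + 1L
    sval <- ti$splitval
    terminal <- ti$terminal
    n_nodes <- nrow(ti)
    pred_cols <- grep("^pred\\.", names(ti))
    leaf_val <- ti[[pred_cols[pos_col]]]

    # node expectations: route the training set, then fold leaf values up
    counts <- route_counts(X_train, left, right, svar, sval, terminal, n_nodes)
    v <- leaf_val
    for (node in rev(which(!terminal))) {
      cl <- counts[left[node]]
      cr <- counts[right[node]]
      v[node] <- (cl * v[left[node]] + cr * v[right[node]]) /
        max(cl + cr, 1L)
    }
    baseline <- baseline + v[1L]

    # credit each split on the prediction path of every target row
    node <- rep(1L, m)
    repeat {
      act <- which(!terminal[node])
      if (!length(act)) break
      cur <- node[act]
      go_left <- x_rows[cbind(act, svar[cur])] <= sval[cur]
      nxt <- ifelse(go_left, left[cur], right[cur])
      contrib[cbind(act, svar[cur])] <-
        contrib[cbind(act, svar[cur])] + v[nxt] - v[cur]
      node[act] <- nxt
    }
  }
  contrib <- contrib / model$num.trees
  baseline <- baseline / model$num.trees
  scores <- stats::predict(model, x_rows, num.threads = 1L)$predictions[, pos_col]
  structure(contrib, baseline = baseline, scores = scores)
}

route_counts <- function(X, left, right, svar, sval, terminal, n_nodes) {
  n <- nrow(X)
  node <- rep(1L, n)
  counts <- integer(n_nodes)
  counts[1L] <- n
  repeat {
    act <- which(!terminal[node])
    if (!length(act)) break
    cur <- node[act]
    go_left <- X[cbind(act, svar[cur])] <= sval[cur]
    node[act] <- ifelse(go_left, left[cur], right[cur])
    counts <- counts + tabulate(node[act], n_nodes)
  }
  counts
}

#' Held-out true positives
#'
#' Only compounds that are predicted active at the chosen threshold and are
#' truly active have valid per-compound attributions; this returns their
#' indices into the held-out test set of a [train_heldout()] fit.
#'
#' @param fit a `heldout_fit`.
#' @return integer vector of row indices into `fit$X_test`.
#' @export
true_positive_rows <- function(fit) {
  which(fit$scores_test >= fit$threshold$threshold & fit$y_test == 1L)
}

#' Overlap of an important-feature set with one term
#'
#' @param important an `important_set` (or character vector of feature
#'   names).
#' @param term a `biomorph_term`.
#' @return percentage in \[0, 100\]: 100 x |important ∩ level-5 features| /
#'   |level-5 features|.
#' @export
term_overlap <- function(important, term) {
  feats <- if (is.character(important)) important else important$feature_names
  100 * length(intersect(feats, term$level5_features)) /
    length(term$level5_features)
}

#' Aggregate per-term overlaps into level enrichments
#'
#' Level-3 (phenotype) and level-4 (cell process) enrichment of a label is
#' the arithmetic mean of the overlap over all terms carrying that label.
#' The hierarchical score propagates upward with the >= 10 % rule: a
#' level-3 label's hierarchical score is the percentage of its terms with
#' overlap >= 10 %, a level-2 label's is the percentage of its level-3
#' labels with hierarchical score >= 10 %, and likewise level 1 over
#' level 2.
#'
#' @param registry a `biomorph_registry`.
#' @param per_term_overlap named numeric vector of overlap percentages
#'   covering every registry term (e.g. from [term_overlap()]).
#' @return an `enrichment_report`: list with `per_term_overlap`,
#'   `level3_enrichment`, `level4_enrichment` (named numeric vectors) and
#'   `hierarchical` (data.frame `level`, `label`, `value`).
#' @export
enrich_levels <- function(registry, per_term_overlap) {
  ids <- vapply(registry$terms, `[[`, character(1L), "term_id")
  miss <- setdiff(ids, names(per_term_overlap))
  if (length(miss)) {
    stop("overlap missing for terms: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ov <- per_term_overlap[ids]
  l1 <- vapply(registry$terms, `[[`, character(1L), "level1_assay")
  l2 <- vapply(registry$terms, `[[`, character(1L), "level2_measurement")
  l3 <- vapply(registry$terms, `[[`, character(1L), "level3_phenotype")
  l4 <- vapply(registry$terms, `[[`, character(1L), "level4_process")

  mean_by <- function(labels) {
    vapply(split(ov, labels), mean, numeric(1L))
  }
  pct_ge10 <- function(values, labels) {
    vapply(split(values, labels), function(v) 100 * mean(v >= 10),
           numeric(1L))
  }

  h3 <- pct_ge10(ov, l3)                       # % of a phenotype's terms
  l3_to_l2 <- tapply(l2, l3, `[`, 1L)          # each readout has one parent
  h2 <- pct_ge10(h3, l3_to_l2[names(h3)])
  l2_to_l1 <- tapply(l1, l2, `[`, 1L)
  h1 <- pct_ge10(h2, l2_to_l1[names(h2)])

  hier <- rbind(
    data.frame(level = 3L, label = names(h3), value = unname(h3)),
    data.frame(level = 2L, label = names(h2), value = unname(h2)),
    data.frame(level = 1L, label = names(h1), value = unname(h1)))
  structure(list(per_term_overlap = ov,
                 level3_enrichment = mean_by(l3),
                 level4_enrichment = mean_by(l4),
                 hierarchical = hier),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("enrichment_report:", length(x$per_term_overlap), "terms |",
      length(x$level3_enrichment), "phenotypes (L3) |",
      length(x$level4_enrichment), "processes (L4)\n")
  top3 <- top_k(x, "level3", 3L)
  if (length(top3)) cat("top phenotypes:", paste(top3, collapse = ", "), "\n")
  invisible(x)
}

#' Top-k enriched labels at one level
#'
#' @param report an `enrichment_report`.
#' @param level `"level3"` or `"level4"`.
#' @param k number of labels (all labels if fewer exist).
#' @return character vector of labels sorted by descending enrichment, ties
#'   broken alphabetically.
#' @export
top_k <- function(report, level = c("level3", "level4"), k = 5L) {
  level <- match.arg(level)
  stopifnot(k >= 1L)
  scores <- report[[paste0(level, "_enrichment")]]
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(min(k, length(scores)))]
}

#' Model-level interpretation in term space
#'
#' Convenience wrapper: takes the impurity importances of a fitted activity
#' model, selects important features with the two-sd rule, computes every
#' term's overlap and aggregates into level enrichments.
#'
#' @param fit a `heldout_fit` (its forest was trained with impurity
#'   importance).
#' @param registry a `biomorph_registry`.
#' @param ... passed to [select_important()].
#' @return an `enrichment_report` with the `important_set` attached as
#'   attribute `important`.
#' @export
interpret_model <- function(fit, registry, ...) {
  imp <- fit$model$variable.importance
  important <- select_important(imp, source = "model_importance", ...)
  report <- overlap_report(important, registry)
  attr(report, "important") <- important
  report
}

#' Per-compound interpretation in term space
#'
#' For each held-out true positive, computes path-based attributions,
#' selects the positively contributing features exceeding the two-sd rule
#' and aggregates term overlaps into level enrichments.
#'
#' @param fit a `heldout_fit`.
#' @param registry a `biomorph_registry`.
#' @param rows indices into the held-out test set; defaults to all true
#'   positives ([true_positive_rows()]).
#' @param ... passed to [select_important()].
#' @return named list (one `enrichment_report` per compound row).
#' @export
interpret_compounds <- function(fit, registry, rows = true_positive_rows(fit),
                                ...) {
  if (!length(rows)) return(list())
  attr_mat <- attribute_compound(fit, fit$X_test[rows, , drop = FALSE])
  out <- lapply(seq_along(rows), function(i) {
    important <- select_important(attr_mat[i, ], positive_only = TRUE,
                                  source = "per_compound_attribution", ...)
    rep <- overlap_report(important, registry)
    attr(rep, "important") <- important
    rep
  })
  names(out) <- rownames(fit$X_test)[rows] %||% as.character(rows)
  out
}

overlap_report <- function(important, registry) {
  ov <- vapply(registry$terms, function(t) term_overlap(important, t),
               numeric(1L))
  names(ov) <- vapply(registry$terms, `[[`, character(1L), "term_id")
  enrich_levels(registry, ov)
}
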