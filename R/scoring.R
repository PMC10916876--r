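#' Score one profile against one term
#'
#' The term-level statistic aggregates a profile's standardized feature
#' values over the term's level-5 subset the way gene-set chi-squared
#' statistics aggregate expression features: under the null hypothesis that
#' the profile behaves like the reference population, each standardized
#' value is approximately standard normal, so the sum of squares over the k
#' subset features follows a chi-squared distribution with k degrees of
#' freedom. The term p-value is the upper-tail probability of that
#' distribution at the observed statistic; small p flags a profile whose
#' morphology is collectively unusual on that term's features.
#'
#' The statistic is pluggable: `statistic_fn(z_subset)` may be replaced, in
#' which case it must return a list with `statistic`, `dof` and `p_value`.
#'
#' @param z_profile named numeric vector of standardized feature values
#'   (standardized against a stated reference population).
#' @param term a `biomorph_term`.
#' @param statistic_fn aggregation statistic; default [chisq_set_statistic()].
#' @return a `term_score`: list with `statistic` (>= 0), `dof` (subset
#'   size) and `p_value` in (0, 1].
#' @export
score_term <- function(z_profile, term, statistic_fn = chisq_set_statistic) {
  missing <- setdiff(term$level5_features, names(z_profile))
  if (length(missing)) {
    stop("profile lacks features required by term ", term$term_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- statistic_fn(z_profile[term$level5_features])
  structure(out, class = "term_score")
}

#' @rdname score_term
#' @param z_subset standardized values restricted to a term's features.
#' @export
chisq_set_statistic <- function(z_subset) {
  stat <- sum(z_subset^2)
  dof <- length(z_subset)
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, df = dof, lower.tail = FALSE))
}

#' @export
print.term_score <- function(x, ...) {
  cat(sprintf("term score: chi2 = %.4f (dof %d), p = %.4g\n",
              x$statistic, x$dof, x$p_value))
  invisible(x)
}

#' Map a profile table into term space
#'
#' Standardizes the profiles against a reference (by default the table
#' itself, matching per-dataset scaling), scores every (profile, term) pair
#' with [score_term()], column-standardizes the resulting p-values and drops
#' term columns that are non-finite anywhere or have zero variance (e.g. a
#' term whose features are constant across the dataset). Terms whose
#' features are absent from the table are dropped up front with a warning.
#'
#' @param profiles a `morph_table` (raw scale; standardization happens
#'   here).
#' @param registry a `biomorph_registry`.
#' @param scaling_reference `"self"` (default) or a list with named vectors
#'   `center` and `scale` (population sd) covering all needed features.
#' @param log10_mode if `TRUE` the matrix holds -log10(p) (p clamped at
#'   1e-300) before column standardization instead of raw p.
#' @param standardize_columns column-standardize the term matrix (the
#'   modelling default); if `FALSE` raw p-values are returned.
#' @return a `biomorph_matrix`: numeric matrix profiles x retained terms
#'   with attributes `retained_terms`, `dropped_terms` and `p_values` (the
#'   raw p-value matrix over all scoreable terms).
#' @export
biomorph_transform <- function(profiles, registry,
                               scaling_reference = "self",
                               log10_mode = FALSE,
                               standardize_columns = TRUE) {
  if (!length(registry$terms)) stop("registry has no terms", call. = FALSE)
  have <- colnames(profiles)
  scoreable <- vapply(registry$terms, function(t)
    all(t$level5_features %in% have), logical(1L))
  if (!all(scoreable)) {
    warning(sum(!scoreable), " term(s) dropped: features absent from the ",
            "profile table", call. = FALSE)
  }
  terms <- registry$terms[scoreable]
  if (!length(terms)) stop("no term is scoreable on this table", call. = FALSE)

  z <- if (identical(scaling_reference, "self")) {
    standardize_features(profiles)
  } else {
    standardize_features(profiles, center = scaling_reference$center,
                         scale = scaling_reference$scale)
  }
  z <- unclass(z)

  ids <- vapply(terms, `[[`, character(1L), "term_id")
  pmat <- matrix(NA_real_, nrow(z), length(terms),
                 dimnames = list(rownames(z), ids))
  for (j in seq_along(terms)) {
    zs <- z[, terms[[j]]$level5_features, drop = FALSE]
    stat <- rowSums(zs^2)
    pmat[, j] <- stats::pchisq(stat, df = ncol(zs), lower.tail = FALSE)
  }

  vals <- if (log10_mode) -log10(pmax(pmat, 1e-300)) else pmat
  if (standardize_columns) {
    mu <- colMeans(vals)
    sdev <- sqrt(colMeans(sweep(vals, 2L, mu)^2))
    vals <- sweep(sweep(vals, 2L, mu), 2L, ifelse(sdev > 0, sdev, 1), `/`)
    bad <- sdev <= 0 | !is.finite(sdev) | colSums(!is.finite(vals)) > 0
  } else {
    bad <- colSums(!is.finite(vals)) > 0
  }
  retained <- ids[!bad]
  if (!length(retained)) {
    stop("zero terms retained after the finiteness/variance filter",
         call. = FALSE)
  }
  out <- vals[, !bad, drop = FALSE]
  structure(out,
            class = c("biomorph_matrix", "matrix", "array"),
            retained_terms = retained,
            dropped_terms = c(ids[bad],
                              vapply(registry$terms[!scoreable], `[[`,
                                     character(1L), "term_id")),
            p_values = pmat)
}

#' @export
print.biomorph_matrix <- function(x, ...) {
  cat("biomorph_matrix:", nrow(x), "profiles x", ncol(x), "retained terms",
      sprintf("(%d dropped)\n", length(attr(x, "dropped_terms"))))
  invisible(x)
}

#' @rdname biomorph_transform
#' @param object a `biomorph_registry`.
#' @param newdata a `morph_table` to transform.
#' @param ... passed to [biomorph_transform()].
#' @export
predict.biomorph_registry <- function(object, newdata, ...) {
  biomorph_transform(newdata, object, ...)
}
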