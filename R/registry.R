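#' Build the term registry from paired profile and cell-health tables
#'
#' The central fitting step. Each candidate term links five annotation
#' levels: assay type (level 1), measurement type (level 2), a specific
#' cell-health phenotype readout (level 3), a perturbed cell process /
#' perturbation group (level 4) and a subset of morphological features
#' (level 5). Construction proceeds per readout:
#'
#' 1. *Step A* — all-relevant selection ([all_relevant_select()], regression
#'    task) finds the features informative for the readout.
#' 2. *Step B* — a baseline linear-regression gate on an 80/20 split must
#'    reach test R-squared > 0.25 ([gate_readout_regression()]).
#' 3. *Step C* — for every non-control perturbation group, all-relevant
#'    selection (classification task) restricted to the step-A subset finds
#'    the features separating that group from the pooled negative controls.
#' 4. *Step D* — a baseline random-forest gate must reach test MCC > 0.50
#'    ([gate_group_classifier()]).
#'
#' Every (readout, group) pair passing both gates becomes one term whose
#' level-5 feature set is the step-C subset (always nested inside the step-A
#' subset). Negative controls are pooled across cell lines, as are group
#' members. All split seeds and selection seeds derive deterministically
#' from `seed` and the readout/group indices.
#'
#' @param profiles a `morph_table` of standardized consensus profiles.
#' @param readouts a `health_table` aligned to `profiles`.
#' @param meta a `perturbation_meta` (or coercible data.frame) with at least
#'   one negative-control row and one non-control group.
#' @param annotations data.frame mapping every readout to its upper levels:
#'   columns `readout_name`, `level1_assay`, `level2_measurement`.
#' @param selection a [selection_config()]; `task` and `seed` are set
#'   per stage internally, the remaining fields (alpha, max_iter, depth,
#'   trees) apply to both selection stages.
#' @param r2_threshold,mcc_threshold strict gate thresholds.
#' @param seed integer master seed.
#' @param verbose print per-readout progress.
#' @return a `biomorph_registry`: list with `terms` (list of
#'   `biomorph_term`), `feature_universe`, `step_a_subsets`, `gate_log`
#'   (data.frame of every gate evaluated) and `provenance`.
#' @seealso [predict.biomorph_registry()] to map profiles into term space,
#'   [write_registry()] / [read_registry()] for serialization.
#' @export
build_registry <- function(profiles, readouts, meta, annotations,
                           selection = selection_config(),
                           r2_threshold = 0.25, mcc_threshold = 0.50,
                           seed = 1L, verbose = FALSE) {
  aligned <- align_tables(profiles, readouts, meta)
  profiles <- aligned$profiles
  readouts <- aligned$readouts
  meta <- aligned$meta

  unmapped <- setdiff(colnames(readouts), annotations$readout_name)
  if (length(unmapped)) {
    stop("no level-1/level-2 annotation for readouts: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  ctrl <- meta$is_negative_control
  groups <- sort(unique(meta$group_label[!ctrl]))
  if (!any(ctrl) || !length(groups)) {
    stop("need >= 1 negative-control row and >= 1 non-control group",
         call. = FALSE)
  }

  terms <- list()
  step_a <- list()
  log_rows <- list()
  for (ri in seq_len(ncol(readouts))) {
    rname <- colnames(readouts)[ri]
    y <- readouts[, ri]
    sel_a <- all_relevant_select(profiles, y, selection_config(
      max_iter = selection$max_iter, alpha = selection$alpha,
      estimator_max_depth = selection$estimator_max_depth,
      estimator_trees = selection$estimator_trees,
      task = "regression", seed = derive_seed(seed, 100L + ri)))
    subset_a <- sel_a$confirmed
    step_a[[rname]] <- subset_a
    if (!length(subset_a)) {
      if (verbose) message(rname, ": step A empty, skipped")
      next
    }
    gate_b <- gate_readout_regression(profiles[, subset_a, drop = FALSE], y,
                                      split_seed = derive_seed(seed, 200L + ri),
                                      threshold = r2_threshold)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      readout = rname, group = NA_character_, stage = "B",
      metric = "r_squared", value = gate_b$value, passed = gate_b$passed)
    if (verbose) message(rname, ": |A| = ", length(subset_a),
                         ", R2 = ", round(gate_b$value, 3))
    if (!gate_b$passed) next

    ann <- annotations[match(rname, annotations$readout_name), ]
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      rows <- which(ctrl | meta$group_label == g & !ctrl)
      is_ctrl <- ctrl[rows]
      sel_c <- all_relevant_select(
        profiles[rows, subset_a, drop = FALSE],
        factor(ifelse(is_ctrl, "control", "group")),
        selection_config(
          max_iter = selection$max_iter, alpha = selection$alpha,
          estimator_max_depth = selection$estimator_max_depth,
          estimator_trees = selection$estimator_trees,
          task = "classification",
          seed = derive_seed(seed, 300L + 1000L * ri + gi)))
      subset_c <- sel_c$confirmed
      if (!length(subset_c)) next
      gate_d <- gate_group_classifier(
        profiles[rows, subset_c, drop = FALSE], is_ctrl,
        split_seed = derive_seed(seed, 400L + 1000L * ri + gi),
        threshold = mcc_threshold)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        readout = rname, group = g, stage = "D", metric = "mcc",
        value = gate_d$value, passed = gate_d$passed)
      if (!gate_d$passed) next
      terms[[length(terms) + 1L]] <- biomorph_term(
        level1_assay = ann$level1_assay,
        level2_measurement = ann$level2_measurement,
        level3_phenotype = rname,
        level4_process = g,
        level5_features = subset_c,
        regression_gate = gate_b,
        classifier_gate = gate_d)
    }
  }

  gate_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(readout = character(), group = character(), stage = character(),
               metric = character(), value = numeric(), passed = logical())
  new_registry(terms,
               feature_universe = colnames(profiles),
               step_a_subsets = step_a,
               gate_log = gate_log,
               provenance = list(
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = as.integer(seed),
                 selection = unclass(selection),
                 r2_threshold = r2_threshold,
                 mcc_threshold = mcc_threshold,
                 profiles_digest = digest::digest(unclass(profiles)),
                 readouts_digest = digest::digest(unclass(readouts))))
}

#' A single term of the registry
#'
#' @param level1_assay,level2_measurement,level3_phenotype,level4_process
#'   annotation labels for levels 1-4; level 3 is a readout name, level 4 a
#'   perturbation-group label.
#' @param level5_features non-empty character vector of feature names.
#' @param regression_gate,classifier_gate `gate_result`s from the build, or
#'   `NULL` for user-authored registries.
#' @return a `biomorph_term` with `term_id` =
#'   `"level1_level2_level3_level4"`.
#' @export
biomorph_term <- function(level1_assay, level2_measurement, level3_phenotype,
                          level4_process, level5_features,
                          regression_gate = NULL, classifier_gate = NULL) {
  level5_features <- as.character(level5_features)
  if (!length(level5_features)) {
    stop("level-5 feature set must be non-empty", call. = FALSE)
  }
  structure(list(
    term_id = paste(level1_assay, level2_measurement, level3_phenotype,
                    level4_process, sep = "_"),
    level1_assay = as.character(level1_assay),
    level2_measurement = as.character(level2_measurement),
    level3_phenotype = as.character(level3_phenotype),
    level4_process = as.character(level4_process),
    level5_features = level5_features,
    regression_gate = regression_gate,
    classifier_gate = classifier_gate),
    class = "biomorph_term")
}

new_registry <- function(terms, feature_universe, step_a_subsets = list(),
                         gate_log = NULL, provenance = list()) {
  ids <- vapply(terms, `[[`, character(1L), "term_id")
  if (anyDuplicated(ids)) {
    stop("duplicate term_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (t in terms) {
    extra <- setdiff(t$level5_features, feature_universe)
    if (length(extra)) {
      stop("term ", t$term_id, " uses features outside the universe: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(terms = terms, feature_universe = feature_universe,
                 step_a_subsets = step_a_subsets, gate_log = gate_log,
                 provenance = provenance),
            class = "biomorph_registry")
}

#' @export
print.biomorph_registry <- function(x, ...) {
  cat("biomorph_registry:", length(x$terms), "terms over",
      length(x$feature_universe), "features\n")
  if (length(x$terms)) {
    ids <- vapply(x$terms, `[[`, character(1L), "term_id")
    cat("terms:", paste(utils::head(sort(ids), 5L), collapse = ", "),
        if (length(ids) > 5L) "..." else "", "\n")
  }
  invisible(x)
}

#' Summarise a term registry
#'
#' @param object a `biomorph_registry`.
#' @param ... unused.
#' @return data.frame with one row per term: the five-level annotation,
#'   subset size and gate values.
#' @export
summary.biomorph_registry <- function(object, ...) {
  if (!length(object$terms)) {
    return(data.frame(term_id = character(), level1 = character(),
                      level2 = character(), level3 = character(),
                      level4 = character(), n_features = integer(),
                      r_squared = numeric(), mcc = numeric()))
  }
  out <- do.call(rbind, lapply(object$terms, function(t) data.frame(
    term_id = t$term_id, level1 = t$level1_assay,
    level2 = t$level2_measurement, level3 = t$level3_phenotype,
    level4 = t$level4_process, n_features = length(t$level5_features),
    r_squared = if (is.null(t$regression_gate)) NA_real_ else
      t$regression_gate$value,
    mcc = if (is.null(t$classifier_gate)) NA_real_ else
      t$classifier_gate$value)))
  out[order(out$term_id), , drop = FALSE]
}

REGISTRY_SCHEMA_VERSION <- "1.0"

#' Serialize a registry to JSON and back
#'
#' The file carries a schema version, the provenance block and the terms
#' sorted by `term_id`, so identical registries serialize to identical
#' bytes.
#'
#' @param registry a `biomorph_registry`.
#' @param path file path (JSON).
#' @return [read_registry()] returns the `biomorph_registry`;
#'   [write_registry()] returns `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  ids <- vapply(registry$terms, `[[`, character(1L), "term_id")
  terms <- lapply(registry$terms[order(ids)], function(t) {
    list(term_id = t$term_id, level1_assay = t$level1_assay,
         level2_measurement = t$level2_measurement,
         level3_phenotype = t$level3_phenotype,
         level4_process = t$level4_process,
         level5_features = as.list(t$level5_features),
         regression_gate = gate_to_list(t$regression_gate),
         classifier_gate = gate_to_list(t$classifier_gate))
  })
  doc <- list(schema_version = REGISTRY_SCHEMA_VERSION,
              provenance = registry$provenance,
              feature_universe = as.list(registry$feature_universe),
              terms = terms)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema_version, REGISTRY_SCHEMA_VERSION)) {
    stop("registry schema version ", doc$schema_version %||% "<missing>",
         " does not match expected ", REGISTRY_SCHEMA_VERSION, call. = FALSE)
  }
  terms <- lapply(doc$terms, function(t) {
    biomorph_term(t$level1_assay, t$level2_measurement, t$level3_phenotype,
                  t$level4_process, unlist(t$level5_features),
                  regression_gate = gate_from_list(t$regression_gate),
                  classifier_gate = gate_from_list(t$classifier_gate))
  })
  new_registry(terms,
               feature_universe = unlist(doc$feature_universe),
               provenance = doc$provenance)
}

gate_to_list <- function(g) {
  if (is.null(g)) return(NULL)
  list(metric_name = g$metric_name, value = g$value, passed = g$passed,
       split_seed = g$split_seed, threshold = g$threshold)
}

gate_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  gate_result(l$metric_name, as.numeric(l$value), l$split_seed,
              as.numeric(l$threshold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
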