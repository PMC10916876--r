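#' Morphological profile and cell-health readout tables
#'
#' A `morph_table` holds one numeric matrix of profiles (rows) by named
#' morphological features (columns); a `health_table` is the same structure
#' for continuous cell-health readouts. Both are plain numeric matrices with
#' mandatory, unique `rownames` (profile identifiers: perturbation x cell
#' line, or compound keys) and `colnames`, carrying an S3 class so that
#' validation happens once at construction.
#'
#' @param values numeric matrix, or an object coercible to one.
#' @param row_ids character vector of unique profile identifiers; defaults to
#'   `rownames(values)`.
#' @param feature_names character vector of unique column names; defaults to
#'   `colnames(values)`.
#' @param na_action `"error"` (default) rejects non-finite cells; `"drop"`
#'   removes rows containing any non-finite cell.
#' @return A validated `morph_table` (resp. `health_table`): a numeric matrix
#'   with class attribute and dimnames set.
#' @examples
#' m <- morph_table(matrix(rnorm(6), 3, 2,
#'   dimnames = list(paste0("p", 1:3), c("f1", "f2"))))
#' @export
morph_table <- function(values, row_ids = rownames(values),
                        feature_names = colnames(values),
                        na_action = c("error", "drop")) {
  new_profile_table(values, row_ids, feature_names, match.arg(na_action),
                    class = "morph_table", what = "feature")
}

#' @rdname morph_table
#' @export
health_table <- function(values, row_ids = rownames(values),
                         feature_names = colnames(values),
                         na_action = c("error", "drop")) {
  new_profile_table(values, row_ids, feature_names, match.arg(na_action),
                    class = "health_table", what = "readout")
}

new_profile_table <- function(values, row_ids, feature_names, na_action,
                              class, what) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("all ", what, " columns must be numeric", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("table must have at least one row and one ", what, call. = FALSE)
  }
  if (is.null(row_ids) || is.null(feature_names)) {
    stop("row identifiers and ", what, " names are mandatory", call. = FALSE)
  }
  row_ids <- as.character(row_ids)
  feature_names <- as.character(feature_names)
  if (anyDuplicated(row_ids)) {
    stop("duplicate row identifiers: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate ", what, " names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(values)
  if (any(bad)) {
    if (na_action == "drop") {
      keep <- rowSums(bad) == 0L
      if (!any(keep)) stop("all rows contain non-finite values", call. = FALSE)
      values <- values[keep, , drop = FALSE]
      row_ids <- row_ids[keep]
    } else {
      stop(sum(bad), " non-finite cells found (set na_action = \"drop\" to ",
           "remove affected rows)", call. = FALSE)
    }
  }
  dimnames(values) <- list(row_ids, feature_names)
  structure(values, class = c(class, "matrix", "array"))
}

#' @export
print.morph_table <- function(x, ...) {
  cat("morph_table:", nrow(x), "profiles x", ncol(x), "features\n")
  invisible(x)
}

#' @export
print.health_table <- function(x, ...) {
  cat("health_table:", nrow(x), "profiles x", ncol(x), "readouts\n")
  invisible(x)
}

# keep the class through row/column subsetting
#' @export
`[.morph_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- class(x)
  out
}

#' @export
`[.health_table` <- `[.morph_table`

#' Read or write a profile/readout table
#'
#' Tables are stored with a mandatory `row_id` first column followed by one
#' numeric column per feature (CSV) or as parquet with the same layout
#' (requires the arrow package).
#'
#' @param path file path; format chosen by extension (`.csv` or `.parquet`).
#' @param schema `"morph"` or `"health"`: which table type to validate as.
#' @param na_action passed to [morph_table()].
#' @return [load_table()] returns a `morph_table` or `health_table`;
#'   [write_table()] returns `path` invisibly.
#' @export
load_table <- function(path, schema = c("morph", "health"),
                       na_action = c("error", "drop")) {
  schema <- match.arg(schema)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_tabular(path)
  if (ncol(df) < 2L || names(df)[1L] != "row_id") {
    stop("expected a header with mandatory first column 'row_id': ", path,
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  vals <- df[-1L]
  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num)) {
    stop("non-numeric columns: ", paste(names(vals)[non_num], collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(vals)
  ctor <- if (schema == "morph") morph_table else health_table
  ctor(m, row_ids = ids, feature_names = colnames(m), na_action = na_action)
}

#' @rdname load_table
#' @param table a `morph_table` or `health_table`.
#' @export
write_table <- function(table, path) {
  df <- data.frame(row_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  if (grepl("\\.parquet$", path)) {
    require_arrow()
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

read_tabular <- function(path) {
  if (grepl("\\.parquet$", path)) {
    require_arrow()
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

require_arrow <- function() {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("parquet support needs the arrow package", call. = FALSE)
  }
}

#' Perturbation metadata
#'
#' Validates a metadata table describing every profile row: which
#' perturbation it comes from, its cell line, the perturbed cell process
#' (group label, e.g. "Chromatin Modifiers") and whether it is a negative
#' control (e.g. LacZ/Luc/Chr2 cutting controls).
#'
#' @param df data.frame with columns `row_id`, `perturbation_id`,
#'   `cell_line`, `group_label`, `is_negative_control`.
#' @param profiles optional `morph_table`; if given, every profile row must
#'   have exactly one metadata record and vice versa.
#' @return the validated data.frame with class `perturbation_meta`.
#' @export
perturbation_meta <- function(df, profiles = NULL) {
  need <- c("row_id", "perturbation_id", "cell_line", "group_label",
            "is_negative_control")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$row_id <- as.character(df$row_id)
  df$is_negative_control <- as.logical(df$is_negative_control)
  if (anyDuplicated(df$row_id)) {
    stop("duplicate row_id in metadata", call. = FALSE)
  }
  if (anyNA(df$is_negative_control)) {
    stop("is_negative_control must be TRUE/FALSE", call. = FALSE)
  }
  if (!is.null(profiles)) {
    if (!setequal(df$row_id, rownames(profiles))) {
      stop("metadata row_ids do not match the profile table", call. = FALSE)
    }
    df <- df[match(rownames(profiles), df$row_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("perturbation_meta", "data.frame")
  df
}

#' Align a readout table (and metadata) to a profile table
#'
#' Reorders rows of `readouts` (and optionally `meta`) to the row order of
#' `profiles`, failing if the identifier sets differ.
#'
#' @param profiles a `morph_table`.
#' @param readouts a `health_table`.
#' @param meta optional `perturbation_meta`.
#' @return list with elements `profiles`, `readouts` and (if given) `meta`.
#' @export
align_tables <- function(profiles, readouts, meta = NULL) {
  if (!setequal(rownames(profiles), rownames(readouts))) {
    stop("profile and readout row identifiers differ", call. = FALSE)
  }
  readouts <- readouts[match(rownames(profiles), rownames(readouts)), ,
                       drop = FALSE]
  out <- list(profiles = profiles, readouts = readouts)
  if (!is.null(meta)) out$meta <- perturbation_meta(meta, profiles)
  out
}

#' Deterministic intersection of feature names
#'
#' Used to restrict two profile datasets (e.g. a gene-perturbation panel and
#' a compound screen) to their common feature universe before mapping either
#' into term space.
#'
#' @param a,b `morph_table`s or character vectors of feature names.
#' @return sorted character vector of common names; error if empty.
#' @export
intersect_features <- function(a, b) {
  fa <- if (is.character(a)) a else colnames(a)
  fb <- if (is.character(b)) b else colnames(b)
  common <- sort(intersect(fa, fb))
  if (!length(common)) {
    stop("feature sets are disjoint: nothing to map", call. = FALSE)
  }
  common
}
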