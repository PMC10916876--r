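#' Subtract the plate-wise neutral-control mean
#'
#' Compound profiles are normalised plate by plate: the average feature value
#' of the neutral (DMSO) control wells on a plate is subtracted from every
#' profile on that plate. Control rows themselves become their deviation from
#' the control mean, so an all-control plate is exactly centred.
#'
#' @param profiles a `morph_table` of per-well or per-perturbation profiles.
#' @param plate_id character/factor vector, one plate label per row.
#' @param control_mask logical vector, `TRUE` for neutral-control rows.
#' @return a `morph_table` of the same shape, control-subtracted per plate.
#' @export
subtract_plate_control <- function(profiles, plate_id, control_mask) {
  stopifnot(length(plate_id) == nrow(profiles),
            length(control_mask) == nrow(profiles))
  plate_id <- as.character(plate_id)
  out <- unclass(profiles)
  for (p in unique(plate_id)) {
    rows <- which(plate_id == p)
    ctrl <- rows[control_mask[rows]]
    if (!length(ctrl)) {
      stop("plate '", p, "' has no control wells", call. = FALSE)
    }
    mu <- colMeans(out[ctrl, , drop = FALSE])
    out[rows, ] <- sweep(out[rows, , drop = FALSE], 2L, mu)
  }
  morph_table(out)
}

#' Collapse a dose series to one consensus profile per compound
#'
#' Where a compound was profiled at several doses, the consensus profile is
#' the per-feature median over the dose points lying within one standard
#' deviation of the mean dose, i.e. points d with |d - mean(d)| <= sd(d).
#' A single dose point (sd undefined, taken as 0) is always retained, and
#' with exactly two points both always fall within one sd of their mean.
#'
#' @param dose_series data.frame with columns `compound_id`, `dose`
#'   (positive), optional `plate_id`, plus one numeric column per feature.
#' @return a `morph_table` with one row per compound (row order = first
#'   appearance), columns = the feature columns.
#' @export
consensus_by_compound <- function(dose_series) {
  need <- c("compound_id", "dose")
  if (!all(need %in% names(dose_series))) {
    stop("dose series needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(dose_series)) stop("empty dose series", call. = FALSE)
  if (any(!is.finite(dose_series$dose)) || any(dose_series$dose <= 0)) {
    stop("doses must be finite and > 0", call. = FALSE)
  }
  feat_cols <- setdiff(names(dose_series), c(need, "plate_id"))
  if (!length(feat_cols)) stop("no feature columns in dose series", call. = FALSE)
  ids <- unique(as.character(dose_series$compound_id))
  out <- matrix(NA_real_, length(ids), length(feat_cols),
                dimnames = list(ids, feat_cols))
  for (id in ids) {
    sub <- dose_series[dose_series$compound_id == id, , drop = FALSE]
    d <- sub$dose
    s <- if (length(d) > 1L) stats::sd(d) else 0
    keep <- abs(d - mean(d)) <= s
    if (!any(keep)) keep <- rep(TRUE, length(d))  # unreachable guard
    out[id, ] <- apply(as.matrix(sub[keep, feat_cols, drop = FALSE]), 2L,
                       stats::median)
  }
  morph_table(out)
}

#' Standardise feature columns to zero mean and unit variance
#'
#' Each column is centred and scaled with the population convention
#' (divisor n), the usual machine-learning scaler default. Zero-variance
#' columns cannot be scaled and map to all-zeros with a warning. Optionally
#' standardises against reference statistics instead of the table's own.
#'
#' @param table a `morph_table` or `health_table` (>= 2 rows for self
#'   standardisation).
#' @param center,scale optional named numeric vectors of reference means and
#'   population standard deviations covering every column; if omitted the
#'   table's own statistics are used.
#' @return a table of the same class with attributes `center` and `scale`
#'   recording the statistics applied.
#' @export
standardize_features <- function(table, center = NULL, scale = NULL) {
  x <- unclass(table)
  if (is.null(center) || is.null(scale)) {
    if (nrow(x) < 2L) stop("need >= 2 rows to self-standardise", call. = FALSE)
    center <- colMeans(x)
    scale <- sqrt(colMeans(sweep(x, 2L, center)^2))  # population sd
  } else {
    miss <- setdiff(colnames(x), names(center))
    miss <- union(miss, setdiff(colnames(x), names(scale)))
    if (length(miss)) {
      stop("reference statistics missing for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    center <- center[colnames(x)]
    scale <- scale[colnames(x)]
  }
  zero_var <- scale <= 0 | !is.finite(scale)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance column(s) set to 0: ",
            paste(utils::head(colnames(x)[zero_var], 5L), collapse = ", "),
            call. = FALSE)
  }
  z <- sweep(x, 2L, center)
  z <- sweep(z, 2L, ifelse(zero_var, 1, scale), `/`)
  z[, zero_var] <- 0
  out <- if (inherits(table, "health_table")) health_table(z) else morph_table(z)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}
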