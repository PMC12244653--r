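#' Extract a feature matrix from an epoch set
#'
#' Computes every registry feature on every epoch record, producing an
#' epochs-by-features matrix with the record metadata alongside. Missing
#' values and infinities returned by features are propagated, never silently
#' replaced. If `discovery_datasets` is given, a per-(feature, channel)
#' validity mask is computed from the discovery records only: a feature is
#' invalid at a channel when it is missing for all discovery epochs there, or
#' constant across all of them.
#'
#' @param x An [epoch_set()] (normally bipolar, preprocessed).
#' @param registry List of [feature_def()]s, e.g.
#'   [default_feature_registry()].
#' @param discovery_datasets Character vector of dataset labels forming the
#'   discovery set, or `NULL` to skip validity masking.
#' @return An object of class `feature_matrix`: list with `values` (numeric
#'   matrix), `meta` (data frame), `feature_names`, `validity` (features x
#'   channels logical matrix, or `NULL`).
#' @export
extract_features <- function(x, registry = default_feature_registry(),
                             discovery_datasets = NULL) {
  stopifnot(inherits(x, "epoch_set"), length(registry) > 0)
  feature_names <- vapply(registry, `[[`, character(1), "name")
  if (anyDuplicated(feature_names)) stop("duplicate feature names in registry")
  n <- nrow(x$samples)
  values <- matrix(NA_real_, n, length(registry),
                   dimnames = list(NULL, feature_names))
  for (j in seq_along(registry)) {
    fn <- registry[[j]]$fn
    values[, j] <- vapply(seq_len(n), function(i) {
      v <- tryCatch(fn(x$samples[i, ], x$sample_rate),
                    error = function(e) NA_real_)
      if (length(v) != 1 || !is.numeric(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  fm <- list(values = values, meta = x$meta, feature_names = feature_names,
             validity = NULL)
  class(fm) <- "feature_matrix"
  if (!is.null(discovery_datasets)) {
    fm$validity <- feature_validity(fm, discovery_datasets)
  }
  fm
}

#' Per-(feature, channel) validity mask
#'
#' A feature is invalid at a channel when its value is missing for all
#' discovery epochs at that channel or constant across all of them (ignoring
#' missing entries for the constancy check).
#'
#' @param fm A `feature_matrix`.
#' @param discovery_datasets Dataset labels forming the discovery set.
#' @return Logical matrix, features x channels (`TRUE` = valid).
#' @export
feature_validity <- function(fm, discovery_datasets) {
  stopifnot(inherits(fm, "feature_matrix"))
  disc <- fm$meta$dataset %in% discovery_datasets
  if (!any(disc)) stop("no discovery records found")
  channels <- sort(unique(fm$meta$channel))
  valid <- matrix(FALSE, length(fm$feature_names), length(channels),
                  dimnames = list(fm$feature_names, as.character(channels)))
  for (ci in seq_along(channels)) {
    rows <- disc & fm$meta$channel == channels[ci]
    v <- fm$values[rows, , drop = FALSE]
    all_missing <- colSums(!is.na(v)) == 0
    constant <- apply(v, 2, function(col) {
      col <- col[!is.na(col)]
      length(col) > 0 && length(unique(col)) == 1
    })
    valid[, ci] <- !(all_missing | constant)
  }
  valid
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d epochs x %d features>\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$validity)) {
    cat(sprintf("  valid (feature, channel) pairs: %d / %d\n",
                sum(x$validity), length(x$validity)))
  }
  invisible(x)
}

#' Subset a feature matrix by epoch records
#'
#' @param fm A `feature_matrix`.
#' @param keep Logical vector over rows.
#' @return A `feature_matrix` with the selected rows (validity mask kept).
#' @export
subset_feature_matrix <- function(fm, keep) {
  stopifnot(inherits(fm, "feature_matrix"), length(keep) == nrow(fm$values))
  out <- fm
  out$values <- fm$values[keep, , drop = FALSE]
  out$meta <- fm$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Tidy data frame view of a feature matrix
#'
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @return Data frame: metadata columns followed by one column per feature.
#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  cbind(x$meta, as.data.frame(x$values))
}

#' Write a feature matrix as tidy CSV
#'
#' @param fm A `feature_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}

#' Outlier-robust sigmoidal scaling to the unit interval
#'
#' Maps feature values through a sigmoid centered on the reference median `m`
#' with slope set by the reference interquartile range `q`,
#' `s(v) = 1 / (1 + exp(-(v - m) / (1.35 q)))`, then min-max rescales by the
#' transformed range of the reference so the reference spans `[0, 1]` exactly.
#' Values outside the reference range saturate at the bounds rather than
#' escaping them. Evaluation flies are scaled with the discovery flies as
#' reference so both sets live on the same scale.
#'
#' @param values Numeric vector to scale (may contain `NA` / `+/-Inf`).
#' @param reference Numeric vector supplying the scaling parameters; defaults
#'   to `values`.
#' @return Numeric vector in `[0, 1]` (`NA` preserved). If the reference IQR
#'   is zero, all outputs are `NA` with a warning.
#' @export
robust_sigmoid_scale <- function(values, reference = values) {
  ref <- reference[is.finite(reference)]
  if (length(ref) == 0) {
    warning("no finite reference values; returning NA")
    return(rep(NA_real_, length(values)))
  }
  m <- stats::median(ref)
  q <- stats::IQR(ref)
  if (q == 0) {
    warning("reference IQR is zero; returning NA")
    return(rep(NA_real_, length(values)))
  }
  sig <- function(v) 1 / (1 + exp(-(v - m) / (1.35 * q)))
  s <- sig(values)
  s_ref <- sig(reference)
  lo <- min(s_ref, na.rm = TRUE)
  hi <- max(s_ref, na.rm = TRUE)
  if (hi == lo) {
    warning("degenerate reference range after sigmoid; returning NA")
    return(rep(NA_real_, length(values)))
  }
  pmin(pmax((s - lo) / (hi - lo), 0), 1)
}
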