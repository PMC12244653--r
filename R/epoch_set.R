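#' Labeled collection of fixed-length signal epochs
#'
#' An `epoch_set` bundles a numeric sample matrix (one row per epoch record,
#' one column per time sample) with per-row metadata identifying the dataset,
#' fly, condition, channel and epoch index of each record. It is the container
#' passed between the generator, the preprocessing stage and feature
#' extraction.
#'
#' @param samples Numeric matrix; rows are epoch records, columns time samples.
#' @param meta Data frame with one row per record and columns `dataset`,
#'   `fly`, `condition`, `channel`, `epoch`.
#' @param sample_rate Sampling rate in Hz.
#' @param signal_type Either `"electrode"` (raw, pre-re-referencing; `channel`
#'   indexes electrodes ordered by depth, 1 = deepest) or `"bipolar"`
#'   (`channel` indexes bipolar channels, 1 = deepest pair).
#' @param provenance Optional description of how the data were produced,
#'   e.g. the [synth_config()] used by [generate_study()].
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(samples, meta, sample_rate,
                      signal_type = c("electrode", "bipolar"),
                      provenance = NULL) {
  signal_type <- match.arg(signal_type)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  required <- c("dataset", "fly", "condition", "channel", "epoch")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("meta is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(meta) != nrow(samples)) {
    stop("meta and samples must have the same number of rows")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  rownames(samples) <- NULL
  x <- list(samples = samples, meta = meta, sample_rate = sample_rate,
            signal_type = signal_type, provenance = provenance)
  class(x) <- "epoch_set"
  validate_epoch_set(x)
  x
}

#' Validate the structural invariants of an epoch set
#'
#' Checks that every (dataset, fly, condition, channel) cell holds the same
#' number of epochs and that the channel set is constant across flies.
#'
#' @param x An `epoch_set`.
#' @return `x`, invisibly; errors if an invariant is violated.
#' @export
validate_epoch_set <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  m <- x$meta
  if (nrow(m) == 0) return(invisible(x))
  cell <- interaction(m$dataset, m$fly, m$condition, m$channel, drop = TRUE)
  counts <- table(cell)
  if (length(unique(counts)) > 1) {
    stop("unequal epoch counts across (dataset, fly, condition, channel) cells")
  }
  ch_per_fly <- tapply(m$channel, interaction(m$dataset, m$fly, drop = TRUE),
                       function(ch) length(unique(ch)))
  if (length(unique(ch_per_fly)) > 1) {
    stop("channel count differs across flies")
  }
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<epoch_set: %d records x %d samples (%s signals, %g Hz)>\n",
              nrow(x$samples), ncol(x$samples), x$signal_type, x$sample_rate))
  cat(sprintf("  datasets: %s\n", paste(unique(m$dataset), collapse = ", ")))
  cat(sprintf("  conditions: %s\n", paste(unique(m$condition), collapse = ", ")))
  cat(sprintf("  flies: %d, channels: %d\n",
              length(unique(paste(m$dataset, m$fly))),
              length(unique(m$channel))))
  invisible(x)
}

#' Subset an epoch set by metadata
#'
#' @param x An `epoch_set`.
#' @param keep Logical vector over records (rows of `x$meta`).
#' @return A new `epoch_set` with the selected records.
#' @export
subset_epoch_set <- function(x, keep) {
  stopifnot(inherits(x, "epoch_set"), is.logical(keep),
            length(keep) == nrow(x$meta))
  epoch_set(x$samples[keep, , drop = FALSE], x$meta[keep, , drop = FALSE],
            x$sample_rate, x$signal_type, x$provenance)
}

#' Write an epoch set to plain-text files
#'
#' The sample matrix goes to `<path>_samples.csv` (no header; rows align with
#' the metadata), per-record metadata to `<path>_meta.csv`, and the sampling
#' rate / signal type / provenance to a `<path>_about.json` sidecar when
#' jsonlite is available (a `dput` sidecar otherwise).
#'
#' @param x An `epoch_set`.
#' @param path Path stem (without extension).
#' @return The path stem, invisibly.
#' @export
write_epoch_set <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  utils::write.table(x$samples, paste0(path, "_samples.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(x$meta, paste0(path, "_meta.csv"), row.names = FALSE)
  about <- list(sample_rate = x$sample_rate, signal_type = x$signal_type,
                provenance = x$provenance)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(about, paste0(path, "_about.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  } else {
    dput(about, file = paste0(path, "_about.R"))
  }
  invisible(path)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param path Path stem used when writing.
#' @return An `epoch_set`.
#' @export
read_epoch_set <- function(path) {
  samples <- as.matrix(utils::read.table(paste0(path, "_samples.csv"),
                                         sep = ",", header = FALSE))
  dimnames(samples) <- NULL
  meta <- utils::read.csv(paste0(path, "_meta.csv"), stringsAsFactors = FALSE)
  json <- paste0(path, "_about.json")
  if (file.exists(json) && requireNamespace("jsonlite", quietly = TRUE)) {
    about <- jsonlite::read_json(json, simplifyVector = TRUE)
  } else {
    about <- dget(paste0(path, "_about.R"))
  }
  epoch_set(samples, meta, about$sample_rate, about$signal_type,
            provenance = about$provenance)
}
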