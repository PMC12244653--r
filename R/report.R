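#' Count features significant across datasets, per channel
#'
#' From a result table with per-dataset FDR flags: for each channel, the
#' number of features significant in every dataset of `require_datasets`
#' (intersection of per-dataset masks), plus the number significant in
#' exactly k datasets for k = 1..K. Rows should already be restricted to one
#' condition pair per dataset and one metric.
#'
#' @param results Result table with `feature`, `channel`, `dataset`,
#'   `fdr_significant` columns.
#' @param require_datasets Dataset labels whose intersection is counted;
#'   defaults to all datasets present.
#' @return List with `intersection` (data frame `channel`, `count`) and
#'   `by_k` (data frame `channel`, `k`, `count`).
#' @export
count_significant <- function(results, require_datasets = NULL) {
  if (is.null(require_datasets)) require_datasets <- unique(results$dataset)
  sub <- results[results$dataset %in% require_datasets, , drop = FALSE]
  channels <- sort(unique(sub$channel))
  inter <- data.frame(channel = channels, count = 0L)
  by_k <- expand.grid(channel = channels, k = seq_along(require_datasets))
  by_k$count <- 0L
  for (ci in seq_along(channels)) {
    ch_rows <- sub[sub$channel == channels[ci], , drop = FALSE]
    n_sig <- tapply(ch_rows$fdr_significant, ch_rows$feature, sum)
    n_seen <- tapply(ch_rows$fdr_significant, ch_rows$feature, length)
    # intersection requires significance in every required dataset
    inter$count[ci] <- sum(n_sig == length(require_datasets) &
                             n_seen == length(require_datasets))
    for (k in seq_along(require_datasets)) {
      by_k$count[by_k$channel == channels[ci] & by_k$k == k] <- sum(n_sig == k)
    }
  }
  list(intersection = inter, by_k = by_k)
}

#' Cluster features by absolute Spearman correlation distance
#'
#' Computes pairwise distances `d = 1 - |Spearman rho|` across epochs
#' (pairwise-complete observations), agglomerates with average linkage, and
#' cuts the tree at the given distance threshold into flat groups. Because
#' Spearman correlation is rank-based, the clustering is invariant to
#' monotone transforms of individual features. Features with fewer than
#' `min_pairs` complete observation pairs against some other feature are
#' excluded.
#'
#' @param values Numeric epochs x features matrix (column names = feature
#'   names), e.g. the significant columns of a `feature_matrix`.
#' @param cut_height Distance threshold for flat groups (default 0.7).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param min_pairs Minimum complete pairs required per feature pair.
#' @return List with `hclust` (the tree), `groups` (named integer vector of
#'   flat group ids), `order` (feature names in dendrogram leaf order), and
#'   `distance` (the `dist` object).
#' @export
cluster_features <- function(values, cut_height = 0.7, linkage = "average",
                             min_pairs = 10) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  finite <- is.finite(values)
  n_pairs <- crossprod(finite)
  ok <- apply(n_pairs >= min_pairs, 1, all)
  if (sum(ok) < 2) stop("fewer than 2 features with enough complete pairs")
  v <- values[, ok, drop = FALSE]
  v[!is.finite(v)] <- NA
  rho <- suppressWarnings(
    stats::cor(v, method = "spearman", use = "pairwise.complete.obs"))
  rho[is.na(rho)] <- 0
  d <- stats::as.dist(1 - abs(rho))
  hc <- stats::hclust(d, method = linkage)
  groups <- stats::cutree(hc, h = cut_height)
  list(hclust = hc, groups = groups, order = hc$labels[hc$order],
       distance = d)
}

#' Run the full synthetic-study analysis pipeline
#'
#' Chains every stage on a generated study: simulation, preprocessing,
#' feature extraction with discovery-based validity masking, leave-one-fly-out
#' cross-validation on the discovery flies with permutation significance,
#' training on all discovery flies, raw and batch-normalized evaluation of
#' every condition pair on the remaining datasets, effect-direction labels,
#' and within-fly consistency with its permutation null.
#'
#' @param config A [synth_config()]; its first dataset label is the discovery
#'   set unless `discovery_dataset` says otherwise.
#' @param registry Feature registry (default: the fast subset, excluding the
#'   O(N^2)-per-epoch features).
#' @param discovery_dataset Label of the discovery dataset.
#' @param n_reps Permutation repetitions for the nulls.
#' @param q FDR level.
#' @param seed Integer seed for the permutation nulls (the study itself is
#'   seeded by `config$seed`).
#' @return List with `epochs` (preprocessed `epoch_set`), `features`
#'   (`feature_matrix`), `classifiers`, `discovery` (LOFO table with
#'   `p_value` / `fdr_significant`), `evaluation_raw`, `evaluation_normalized`
#'   (result tables; `NULL` when there is no evaluation dataset), `labels`,
#'   and `consistency`.
#' @export
run_synthetic_pipeline <- function(config,
                                   registry = default_feature_registry(include_expensive = FALSE),
                                   discovery_dataset = names(config$datasets)[1],
                                   n_reps = 7702, q = 0.05, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  raw <- generate_study(config)
  pp <- preprocess_epochs(raw, preprocess_params(
    epoch_seconds = config$epoch_seconds, sample_rate = config$sample_rate,
    line_freq = config$line_noise_hz))
  fm <- extract_features(pp, registry, discovery_datasets = discovery_dataset)
  wake <- config$wake_conditions
  unc <- config$unconscious_conditions

  disc_fm <- subset_feature_matrix(fm, fm$meta$dataset == discovery_dataset)
  lofo <- lofo_cross_validate(disc_fm, wake, unc)
  null_disc <- permutation_null_accuracy(
    sum(disc_fm$meta$condition %in% wake & disc_fm$meta$channel == disc_fm$meta$channel[1]),
    sum(disc_fm$meta$condition %in% unc & disc_fm$meta$channel == disc_fm$meta$channel[1]),
    n_reps, seed = seed)
  lofo$p_value <- permutation_p_value(lofo$mean_accuracy, null_disc)
  lofo$fdr_significant <- FALSE
  for (ch in unique(lofo$channel)) {
    sel <- lofo$channel == ch
    lofo$fdr_significant[sel] <- fdr_correct(lofo$p_value[sel], q)$significant
  }

  clfs <- train_classifiers(disc_fm, wake, unc)
  labels <- effect_direction_labels(disc_fm, wake, unc)

  eval_sets <- setdiff(unique(fm$meta$dataset), discovery_dataset)
  evaluation_raw <- evaluation_normalized <- consistency <- NULL
  if (length(eval_sets) > 0) {
    eval_fm <- subset_feature_matrix(fm, fm$meta$dataset %in% eval_sets)
    evaluation_raw <- add_accuracy_significance(
      evaluate_condition_pairs(clfs, eval_fm, wake_conditions = wake,
                               unconscious_conditions = unc,
                               normalized = FALSE),
      n_reps, q, seed = seed + 1000L)
    eval_norm <- normalize_feature_matrix(eval_fm, disc_fm)
    evaluation_normalized <- add_accuracy_significance(
      evaluate_condition_pairs(clfs, eval_norm, wake_conditions = wake,
                               unconscious_conditions = unc,
                               normalized = TRUE),
      n_reps, q, seed = seed + 2000L)
    consistency <- consistency_results(labels, eval_fm,
                                       wake_conditions = wake,
                                       unconscious_conditions = unc,
                                       n_reps = n_reps, q = q,
                                       seed = seed + 3000L)
  }
  list(epochs = pp, features = fm, classifiers = clfs, discovery = lofo,
       evaluation_raw = evaluation_raw,
       evaluation_normalized = evaluation_normalized,
       labels = labels, consistency = consistency)
}
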