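#' Effect direction from class medians
#'
#' Shared rule behind the nearest-median classifier direction and the
#' effect-direction labels of the consistency analysis: +1 when the median
#' wakeful value exceeds the median unconscious value, -1 when it is smaller.
#' Equal medians are degenerate; the classifier breaks the tie to +1 while
#' the literal labeling rule ("-1 otherwise") breaks it to -1, controlled by
#' `tie`.
#'
#' @param median_wake,median_unconscious Class medians (may be infinite).
#' @param tie Direction assigned when the medians are equal.
#' @return `+1` or `-1`.
#' @export
median_direction <- function(median_wake, median_unconscious, tie = 1) {
  if (is.na(median_wake) || is.na(median_unconscious)) return(NA_real_)
  if (median_wake > median_unconscious) 1
  else if (median_wake < median_unconscious) -1
  else tie
}

#' Fit a nearest-median classifier for one feature and channel
#'
#' The threshold is the midpoint between the median feature value under
#' wakefulness and under the unconscious condition (medians are order
#' statistics, so infinite values participate); the direction says whether
#' values above the threshold are classified as wakeful (+1) or unconscious
#' (-1). Epochs exactly on the threshold are classified unconscious.
#'
#' @param wake_values,unconscious_values Numeric vectors of training feature
#'   values (`NA` dropped; `+/-Inf` allowed).
#' @return An object of class `median_classifier`: list with `threshold`,
#'   `direction`, `degenerate` (equal medians), `median_wake`,
#'   `median_unconscious`.
#' @export
fit_classifier <- function(wake_values, unconscious_values) {
  w <- wake_values[!is.na(wake_values)]
  u <- unconscious_values[!is.na(unconscious_values)]
  if (length(w) == 0 || length(u) == 0) {
    stop("each class needs at least one non-missing value")
  }
  mw <- stats::median(w)
  mu <- stats::median(u)
  clf <- list(threshold = (mw + mu) / 2,
              direction = median_direction(mw, mu, tie = 1),
              degenerate = mw == mu,
              median_wake = mw, median_unconscious = mu)
  class(clf) <- "median_classifier"
  clf
}

#' Classification accuracy of a fitted nearest-median classifier
#'
#' An epoch with value `v` is classified wakeful iff
#' `direction * (v - threshold) > 0` (ties go to unconscious). Accuracy is
#' the fraction of correct labels pooled over both conditions; missing values
#' cannot be classified and count as incorrect.
#'
#' @param clf A [fit_classifier()] result.
#' @param wake_values,unconscious_values Feature values of the test epochs.
#' @return Accuracy in `[0, 1]`.
#' @export
predict_accuracy <- function(clf, wake_values, unconscious_values) {
  stopifnot(inherits(clf, "median_classifier"))
  as_wake_w <- clf$direction * (wake_values - clf$threshold) > 0
  as_wake_u <- clf$direction * (unconscious_values - clf$threshold) > 0
  correct <- sum(as_wake_w, na.rm = TRUE) + sum(!as_wake_u, na.rm = TRUE)
  correct / (length(wake_values) + length(unconscious_values))
}

# Pull (feature, channel) training vectors out of a feature matrix.
fm_values <- function(fm, feature, channel, conditions, datasets = NULL,
                      flies = NULL) {
  m <- fm$meta
  rows <- m$channel == channel & m$condition %in% conditions
  if (!is.null(datasets)) rows <- rows & m$dataset %in% datasets
  if (!is.null(flies)) rows <- rows & m$fly %in% flies
  fm$values[rows, feature]
}

#' Train nearest-median classifiers for every valid (feature, channel) pair
#'
#' @param fm A `feature_matrix` (typically the discovery flies).
#' @param wake_conditions,unconscious_conditions Condition labels treated as
#'   wakeful / unconscious during training.
#' @param datasets Dataset labels to train on (default: all in `fm`).
#' @return Data frame with one row per trained (feature, channel):
#'   `feature`, `channel`, `threshold`, `direction`, `degenerate`.
#' @export
train_classifiers <- function(fm, wake_conditions = "wake",
                              unconscious_conditions = "anesthesia",
                              datasets = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(datasets)) datasets <- unique(fm$meta$dataset)
  channels <- sort(unique(fm$meta$channel))
  rows <- list()
  for (ch in channels) {
    for (f in fm$feature_names) {
      if (!is.null(fm$validity) &&
          !fm$validity[f, as.character(ch)]) next
      w <- fm_values(fm, f, ch, wake_conditions, datasets)
      u <- fm_values(fm, f, ch, unconscious_conditions, datasets)
      if (all(is.na(w)) || all(is.na(u))) next
      clf <- fit_classifier(w, u)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, channel = ch, threshold = clf$threshold,
        direction = clf$direction, degenerate = clf$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Leave-one-fly-out cross-validation on the discovery flies
#'
#' One fold per fly: classifiers are trained on all epochs of the remaining
#' flies and tested on the held-out fly's epochs, measuring across-individual
#' generalization. Reports mean and SD of fold accuracies per (feature,
#' channel).
#'
#' @inheritParams train_classifiers
#' @return Data frame: `feature`, `channel`, `mean_accuracy`, `sd_accuracy`,
#'   `n_folds`, `n_test_epochs` (total test epochs pooled over folds).
#' @export
lofo_cross_validate <- function(fm, wake_conditions = "wake",
                                unconscious_conditions = "anesthesia",
                                datasets = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(datasets)) datasets <- unique(fm$meta$dataset)
  keep <- fm$meta$dataset %in% datasets
  fm <- subset_feature_matrix(fm, keep)
  flies <- unique(fm$meta$fly)
  channels <- sort(unique(fm$meta$channel))
  rows <- list()
  for (ch in channels) {
    for (f in fm$feature_names) {
      if (!is.null(fm$validity) && !fm$validity[f, as.character(ch)]) next
      acc <- rep(NA_real_, length(flies))
      n_test <- 0L
      ok <- TRUE
      for (i in seq_along(flies)) {
        w_tr <- fm_values(fm, f, ch, wake_conditions, flies = setdiff(flies, flies[i]))
        u_tr <- fm_values(fm, f, ch, unconscious_conditions,
                          flies = setdiff(flies, flies[i]))
        if (all(is.na(w_tr)) || all(is.na(u_tr))) { ok <- FALSE; break }
        clf <- fit_classifier(w_tr, u_tr)
        w_te <- fm_values(fm, f, ch, wake_conditions, flies = flies[i])
        u_te <- fm_values(fm, f, ch, unconscious_conditions, flies = flies[i])
        acc[i] <- predict_accuracy(clf, w_te, u_te)
        n_test <- n_test + length(w_te) + length(u_te)
      }
      if (!ok) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, channel = ch, mean_accuracy = mean(acc),
        sd_accuracy = stats::sd(acc), n_folds = length(flies),
        n_test_epochs = n_test, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate trained classifiers on every wake/unconscious condition pair
#'
#' For each evaluation dataset, pairs each wake-like condition with each
#' unconscious-like condition and scores the discovery-trained classifier of
#' every (feature, channel) on the pooled epochs of the pair. Equal epoch
#' counts across conditions make chance accuracy exactly 50%.
#'
#' @param classifiers Data frame from [train_classifiers()].
#' @param fm Evaluation `feature_matrix`.
#' @param pairing Data frame with columns `dataset`, `wake`, `unconscious`
#'   naming the condition pairs to evaluate, or `NULL` to cross every
#'   wake-like condition with every unconscious-like condition present in
#'   each dataset.
#' @param wake_conditions,unconscious_conditions Labels used to build the
#'   default pairing.
#' @param normalized Logical flag recorded in the output (set it when `fm`
#'   has been batch-normalized).
#' @return A result table (data frame): `feature`, `channel`, `dataset`,
#'   `condition_pair`, `metric = "accuracy"`, `value`, `n_wake`,
#'   `n_unconscious`, `normalized`.
#' @export
evaluate_condition_pairs <- function(classifiers, fm, pairing = NULL,
                                     wake_conditions = "wake",
                                     unconscious_conditions = "anesthesia",
                                     normalized = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(pairing)) {
    pairing <- do.call(rbind, lapply(unique(fm$meta$dataset), function(d) {
      conds <- unique(fm$meta$condition[fm$meta$dataset == d])
      expand.grid(dataset = d,
                  wake = intersect(wake_conditions, conds),
                  unconscious = intersect(unconscious_conditions, conds),
                  stringsAsFactors = FALSE)
    }))
  }
  if (is.null(pairing) || nrow(pairing) == 0) {
    return(data.frame(feature = character(), channel = integer(),
                      dataset = character(), condition_pair = character(),
                      metric = character(), value = numeric(),
                      n_wake = integer(), n_unconscious = integer(),
                      normalized = logical(), stringsAsFactors = FALSE))
  }
  rows <- vector("list", nrow(classifiers) * nrow(pairing))
  r <- 0L
  for (p in seq_len(nrow(pairing))) {
    d <- pairing$dataset[p]
    for (i in seq_len(nrow(classifiers))) {
      f <- classifiers$feature[i]
      ch <- classifiers$channel[i]
      clf <- structure(list(threshold = classifiers$threshold[i],
                            direction = classifiers$direction[i]),
                       class = "median_classifier")
      w <- fm_values(fm, f, ch, pairing$wake[p], d)
      u <- fm_values(fm, f, ch, pairing$unconscious[p], d)
      if (length(w) == 0 || length(u) == 0) next
      r <- r + 1L
      rows[[r]] <- data.frame(
        feature = f, channel = ch, dataset = d,
        condition_pair = paste(pairing$wake[p], pairing$unconscious[p],
                               sep = " vs "),
        metric = "accuracy", value = predict_accuracy(clf, w, u),
        n_wake = length(w), n_unconscious = length(u),
        normalized = normalized, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(r)])
}

#' Batch normalization of evaluation feature values
#'
#' Removes dataset-level shifts by z-scoring evaluation values with the
#' evaluation set's own mean and SD and back-transforming with the discovery
#' mean and SD: `v' = (v - m_eval) / s_eval * s_disc + m_disc`. Infinite
#' values are ignored when computing the moments and remain infinite after
#' normalization; missing values stay missing.
#'
#' @param values Numeric vector of evaluation values.
#' @param eval_mean,eval_sd Moments of the evaluation reference (finite
#'   values of all epochs of the evaluation set).
#' @param disc_mean,disc_sd Moments of the discovery reference.
#' @return Normalized numeric vector.
#' @export
batch_normalize <- function(values, eval_mean, eval_sd, disc_mean, disc_sd) {
  if (!is.finite(eval_sd) || eval_sd <= 0) {
    stop("evaluation reference SD must be positive")
  }
  out <- (values - eval_mean) / eval_sd * disc_sd + disc_mean
  out[is.infinite(values)] <- values[is.infinite(values)]
  out
}

#' Batch-normalize a whole evaluation feature matrix
#'
#' Applies [batch_normalize()] per (feature, channel), using all epochs of
#' each evaluation dataset as its own reference and all discovery epochs as
#' the target. Features whose evaluation SD is zero are set to missing for
#' that dataset/channel.
#'
#' @param fm_eval Evaluation `feature_matrix`.
#' @param fm_disc Discovery `feature_matrix`.
#' @return A `feature_matrix` with normalized values.
#' @export
normalize_feature_matrix <- function(fm_eval, fm_disc) {
  stopifnot(inherits(fm_eval, "feature_matrix"),
            inherits(fm_disc, "feature_matrix"))
  out <- fm_eval
  for (d in unique(fm_eval$meta$dataset)) {
    for (ch in sort(unique(fm_eval$meta$channel))) {
      er <- fm_eval$meta$dataset == d & fm_eval$meta$channel == ch
      dr <- fm_disc$meta$channel == ch
      for (f in fm_eval$feature_names) {
        if (!f %in% fm_disc$feature_names) next
        ev <- fm_eval$values[er, f]
        dv <- fm_disc$values[dr, f]
        me <- mean(ev[is.finite(ev)])
        se <- stats::sd(ev[is.finite(ev)])
        md <- mean(dv[is.finite(dv)])
        sd_ <- stats::sd(dv[is.finite(dv)])
        if (!is.finite(se) || se == 0 || !is.finite(sd_)) {
          out$values[er, f] <- NA_real_
        } else {
          out$values[er, f] <- batch_normalize(ev, me, se, md, sd_)
        }
      }
    }
  }
  out
}

#' Random-classification null distribution of accuracy
#'
#' Labels each of the `n_wake + n_unconscious` epochs wakeful or unconscious
#' independently with probability 1/2 and records the resulting accuracy, so
#' each draw is `Binomial(n, 1/2) / n` (drawn directly as a binomial count).
#' The null mean is 50%, matching chance for balanced condition pairs.
#'
#' @param n_wake,n_unconscious Epoch counts.
#' @param n_reps Number of repetitions (default 7702, one per candidate
#'   feature in the full library).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n_reps` null accuracies.
#' @export
permutation_null_accuracy <- function(n_wake, n_unconscious, n_reps = 7702,
                                      seed = NULL) {
  stopifnot(n_wake >= 1, n_unconscious >= 1, n_reps >= 1)
  n <- n_wake + n_unconscious
  draw <- function() stats::rbinom(n_reps, n, 0.5) / n
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Permutation p-value of an observed statistic
#'
#' Upper-tail p-value with the add-one correction,
#' `(1 + #\{null >= observed\}) / (n_reps + 1)`, which avoids p = 0 and
#' recovers the empirical quantile as the repetition count grows.
#'
#' @param observed Observed statistic (scalar or vector).
#' @param null_values Numeric vector of null draws.
#' @return p-values in `(0, 1]`.
#' @export
permutation_p_value <- function(observed, null_values) {
  vapply(observed, function(o) {
    if (is.na(o)) return(NA_real_)
    (1 + sum(null_values >= o)) / (length(null_values) + 1)
  }, numeric(1))
}

#' Benjamini-Hochberg FDR correction within a channel
#'
#' Step-up FDR control at level `q` across the valid features of one channel
#' (BH remains valid under the positive dependency expected among related
#' features, e.g. autocorrelations at neighboring lags).
#'
#' @param p_values Numeric vector of p-values (NA allowed, never significant).
#' @param q FDR level.
#' @return List with `significant` (logical mask) and `threshold` (the
#'   adaptive p-value cutoff; 0 when nothing is significant).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  adj <- stats::p.adjust(p_values, method = "BH")
  sig <- !is.na(adj) & adj <= q
  threshold <- if (any(sig)) max(p_values[sig], na.rm = TRUE) else 0
  list(significant = sig, threshold = threshold)
}

#' Attach permutation p-values and per-channel FDR flags to a result table
#'
#' Computes, for every row of an accuracy result table, the permutation
#' p-value against the random-classification null for its epoch counts
#' (nulls are shared across rows with equal counts), then applies
#' Benjamini-Hochberg FDR at level `q` across features within each
#' (channel, dataset, condition pair, normalized) group.
#'
#' @param results Result table from [evaluate_condition_pairs()] or a
#'   compatible data frame with `value`, `n_wake`, `n_unconscious` columns.
#' @param n_reps Permutation repetitions.
#' @param q FDR level.
#' @param seed Integer seed for the null draws.
#' @return The result table with `p_value` and `fdr_significant` columns.
#' @export
add_accuracy_significance <- function(results, n_reps = 7702, q = 0.05,
                                      seed = 1L) {
  if (nrow(results) == 0) {
    results$p_value <- numeric(0)
    results$fdr_significant <- logical(0)
    return(results)
  }
  counts <- unique(results[, c("n_wake", "n_unconscious")])
  nulls <- lapply(seq_len(nrow(counts)), function(i) {
    permutation_null_accuracy(counts$n_wake[i], counts$n_unconscious[i],
                              n_reps, seed = seed + i)
  })
  key <- paste(results$n_wake, results$n_unconscious)
  null_key <- paste(counts$n_wake, counts$n_unconscious)
  results$p_value <- NA_real_
  for (i in seq_len(nrow(counts))) {
    rows <- key == null_key[i]
    results$p_value[rows] <- permutation_p_value(results$value[rows],
                                                 nulls[[i]])
  }
  grp <- interaction(results$channel, results$dataset, results$condition_pair,
                     results$normalized, drop = TRUE)
  results$fdr_significant <- FALSE
  for (g in levels(grp)) {
    rows <- grp == g
    results$fdr_significant[rows] <- fdr_correct(results$p_value[rows], q)$significant
  }
  results
}
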