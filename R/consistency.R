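#' Effect-direction labels from the discovery flies
#'
#' For each trained (feature, channel): +1 if the discovery median wakeful
#' value exceeds the median unconscious value, -1 otherwise (the literal
#' labeling rule; equal medians are flagged degenerate). Shares
#' [median_direction()] with the classifier.
#'
#' @param fm Discovery `feature_matrix`.
#' @param wake_conditions,unconscious_conditions Condition labels.
#' @param datasets Dataset labels to use (default all).
#' @return Data frame: `feature`, `channel`, `label`, `degenerate`.
#' @export
effect_direction_labels <- function(fm, wake_conditions = "wake",
                                    unconscious_conditions = "anesthesia",
                                    datasets = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(datasets)) datasets <- unique(fm$meta$dataset)
  rows <- list()
  for (ch in sort(unique(fm$meta$channel))) {
    for (f in fm$feature_names) {
      if (!is.null(fm$validity) && !fm$validity[f, as.character(ch)]) next
      w <- fm_values(fm, f, ch, wake_conditions, datasets)
      u <- fm_values(fm, f, ch, unconscious_conditions, datasets)
      if (all(is.na(w)) || all(is.na(u))) next
      mw <- stats::median(w, na.rm = TRUE)
      mu <- stats::median(u, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, channel = ch,
        label = median_direction(mw, mu, tie = -1),
        degenerate = mw == mu, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Within-fly effect-direction consistency
#'
#' After multiplying all values by the discovery-derived direction label, each
#' wakeful epoch of a fly contributes the proportion of that same fly's
#' unconscious epochs lying strictly below it (ties count as not below). The
#' statistic is the unweighted mean of these proportions over all wakeful
#' epochs of all flies, so flies are weighted by their wake-epoch counts
#' (set `equal_fly_weight = TRUE` to average per-fly means instead). It is 1
#' when the effect direction is conserved for every within-fly pairing, 0
#' when it is reversed for every pairing, and 0.5 at chance. Because it only
#' uses within-fly rank information, it is invariant to any strictly
#' increasing per-fly transform of the values - unlike classification
#' accuracy, which a fly- or dataset-level offset can destroy.
#'
#' @param wake_by_fly,unconscious_by_fly Named lists (same fly names) of
#'   numeric feature-value vectors. Flies missing either class are excluded.
#' @param label Direction label (+1 or -1).
#' @param equal_fly_weight Weight flies equally instead of by wake-epoch
#'   count?
#' @return Consistency in `[0, 1]`, or `NA` if no fly has both classes.
#' @export
within_fly_consistency <- function(wake_by_fly, unconscious_by_fly, label,
                                   equal_fly_weight = FALSE) {
  stopifnot(label %in% c(-1, 1))
  flies <- intersect(names(wake_by_fly), names(unconscious_by_fly))
  props <- list()
  for (f in flies) {
    w <- label * wake_by_fly[[f]]
    u <- label * unconscious_by_fly[[f]]
    w <- w[!is.na(w)]
    u <- u[!is.na(u)]
    if (length(w) == 0 || length(u) == 0) next
    props[[f]] <- vapply(w, function(v) mean(u < v), numeric(1))
  }
  if (length(props) == 0) return(NA_real_)
  if (equal_fly_weight) {
    mean(vapply(props, mean, numeric(1)))
  } else {
    mean(unlist(props))
  }
}

#' Permutation null distribution of the consistency statistic
#'
#' Each repetition randomly assigns, for every wakeful epoch of every fly,
#' the proportion of that fly's unconscious epochs lying below it, drawn
#' uniformly from the achievable set `{0, 1/n_u, ..., 1}`, and averages over
#' all wakeful epochs and flies. The null mean is 0.5.
#'
#' @param epoch_counts Data frame with one row per fly and columns `n_wake`
#'   and `n_unconscious`.
#' @param n_reps Number of repetitions (default 7702).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_reps` null consistency values.
#' @export
permutation_null_consistency <- function(epoch_counts, n_reps = 7702,
                                         seed = NULL) {
  stopifnot(all(epoch_counts$n_wake >= 1), all(epoch_counts$n_unconscious >= 1))
  draw <- function() {
    total_wake <- sum(epoch_counts$n_wake)
    acc <- numeric(n_reps)
    for (i in seq_len(nrow(epoch_counts))) {
      nw <- epoch_counts$n_wake[i]
      nu <- epoch_counts$n_unconscious[i]
      prop <- (sample.int(nu + 1, nw * n_reps, replace = TRUE) - 1) / nu
      acc <- acc + colSums(matrix(prop, nrow = nw, ncol = n_reps))
    }
    acc / total_wake
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Consistency of every (feature, channel) on an evaluation set
#'
#' Evaluates [within_fly_consistency()] for each labeled (feature, channel)
#' on every wake/unconscious condition pair of each evaluation dataset, with
#' permutation p-values and per-channel Benjamini-Hochberg FDR flags.
#'
#' @param labels Data frame from [effect_direction_labels()].
#' @param fm Evaluation `feature_matrix`.
#' @param pairing Data frame (`dataset`, `wake`, `unconscious`) of condition
#'   pairs, or `NULL` to cross all wake-like and unconscious-like conditions
#'   present per dataset.
#' @param wake_conditions,unconscious_conditions Labels used for the default
#'   pairing.
#' @param n_reps Permutation repetitions.
#' @param q FDR level.
#' @param seed Integer seed for the permutation nulls.
#' @param equal_fly_weight Passed to [within_fly_consistency()].
#' @return Result table: `feature`, `channel`, `dataset`, `condition_pair`,
#'   `metric = "consistency"`, `value`, `p_value`, `fdr_significant`.
#' @export
consistency_results <- function(labels, fm, pairing = NULL,
                                wake_conditions = "wake",
                                unconscious_conditions = "anesthesia",
                                n_reps = 7702, q = 0.05, seed = 1L,
                                equal_fly_weight = FALSE) {
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
  m <- fm$meta
  rows <- list()
  null_cache <- list()
  for (p in seq_len(nrow(pairing))) {
    d <- pairing$dataset[p]
    flies <- unique(m$fly[m$dataset == d])
    counts <- data.frame(
      n_wake = vapply(flies, function(fl) {
        sum(m$dataset == d & m$fly == fl & m$condition == pairing$wake[p] &
              m$channel == m$channel[1])
      }, numeric(1)),
      n_unconscious = vapply(flies, function(fl) {
        sum(m$dataset == d & m$fly == fl &
              m$condition == pairing$unconscious[p] & m$channel == m$channel[1])
      }, numeric(1)))
    counts <- counts[counts$n_wake >= 1 & counts$n_unconscious >= 1, ,
                     drop = FALSE]
    if (nrow(counts) == 0) next
    ckey <- paste(counts$n_wake, counts$n_unconscious, collapse = ";")
    if (is.null(null_cache[[ckey]])) {
      null_cache[[ckey]] <- permutation_null_consistency(counts, n_reps,
                                                         seed = seed + p)
    }
    null_values <- null_cache[[ckey]]
    for (i in seq_len(nrow(labels))) {
      f <- labels$feature[i]
      ch <- labels$channel[i]
      wl <- list()
      ul <- list()
      for (fl in flies) {
        sel <- m$dataset == d & m$fly == fl & m$channel == ch
        wl[[fl]] <- fm$values[sel & m$condition == pairing$wake[p], f]
        ul[[fl]] <- fm$values[sel & m$condition == pairing$unconscious[p], f]
      }
      val <- within_fly_consistency(wl, ul, labels$label[i],
                                    equal_fly_weight = equal_fly_weight)
      if (is.na(val)) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, channel = ch, dataset = d,
        condition_pair = paste(pairing$wake[p], pairing$unconscious[p],
                               sep = " vs "),
        metric = "consistency", value = val,
        p_value = permutation_p_value(val, null_values),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  if (is.null(results)) return(NULL)
  grp <- interaction(results$channel, results$dataset,
                     results$condition_pair, drop = TRUE)
  results$fdr_significant <- FALSE
  for (g in levels(grp)) {
    sel <- grp == g
    results$fdr_significant[sel] <- fdr_correct(results$p_value[sel], q)$significant
  }
  results
}
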