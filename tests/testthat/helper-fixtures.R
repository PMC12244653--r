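# Shared fixtures, built in code at load time.

# Small two-dataset study with a strong-effect, a medium-effect and a
# zero-effect channel, and a gain-only batch shift in the evaluation set.
small_config <- function(seed = 7, ...) {
  synth_config(datasets = c(discovery = 6, evaluation = 5),
               n_electrodes = 4,
               channel_effect_profile = c(1, 0.6, 0),
               batch_gain = c(evaluation = 3),
               seed = seed, ...)
}

# Build a feature_matrix directly from per-epoch feature values, bypassing
# signal generation, for classifier/consistency unit tests.
make_fm <- function(df, feature_cols) {
  meta_cols <- c("dataset", "fly", "condition", "channel", "epoch")
  stopifnot(all(meta_cols %in% names(df)))
  fm <- list(values = as.matrix(df[, feature_cols, drop = FALSE]),
             meta = df[, meta_cols],
             feature_names = feature_cols,
             validity = NULL)
  class(fm) <- "feature_matrix"
  fm
}

# Brute-force consistency oracle: explicit enumeration over all
# (wake epoch, unconscious epoch) pairs per fly.
brute_force_consistency <- function(wake_by_fly, unc_by_fly, label) {
  props <- c()
  for (f in names(wake_by_fly)) {
    w <- label * wake_by_fly[[f]]
    u <- label * unc_by_fly[[f]]
    for (wv in w) {
      below <- 0
      for (uv in u) if (uv < wv) below <- below + 1
      props <- c(props, below / length(u))
    }
  }
  mean(props)
}

# Brute-force biased-normalization autocorrelation oracle.
brute_force_ac <- function(x, k) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (t in 1:(n - k)) num <- num + (x[t] - xb) * (x[t + k] - xb)
  num / sum((x - xb)^2)
}

# Step-up Benjamini-Hochberg oracle by direct enumeration.
bh_step_up <- function(p, q) {
  m <- length(p)
  o <- order(p)
  passed <- which(p[o] <= q * seq_len(m) / m)
  sig <- rep(FALSE, m)
  if (length(passed) > 0) sig[o[seq_len(max(passed))]] <- TRUE
  sig
}
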