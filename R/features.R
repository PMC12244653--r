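#' Autocorrelation at a fixed lag
#'
#' Sample autocorrelation with the biased normalization,
#' `r_k = sum_{t=1}^{N-k} (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`,
#' the standard estimator (it stabilizes high lags and guarantees a valid
#' autocorrelation sequence). At 1000 Hz, lag `k` corresponds to `k` ms, so
#' `ac_lag(x, 30)` probes the ~30 ms timescale at which wakeful fly LFP is
#' more autocorrelated than anesthetized LFP. Invariant to affine transforms
#' of `x`.
#'
#' @param x Numeric vector.
#' @param k Lag in samples, `0 <= k < length(x)`; lag 0 returns 1.
#' @return Autocorrelation in `[-1, 1]`, or `NA` for constant input.
#' @export
ac_lag <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 0, n > k)
  if (k == 0) return(1)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(NA_real_)
  sum(xc[1:(n - k)] * xc[(k + 1):n]) / denom
}

#' Local-mean stationarity index (StatAv)
#'
#' Ratio of the SD of non-overlapping local window means to the global SD
#' (both with the N-1 denominator). Low values indicate a mean-stationary
#' signal; a drifting mean inflates the index. The 250-sample window at
#' 1000 Hz matches the StatAvl250 feature.
#'
#' @param x Numeric vector with `length(x) >= 2 * window_len`.
#' @param window_len Window length in samples.
#' @return Non-negative scalar, or `NA` for constant input.
#' @export
statav_local <- function(x, window_len = 250) {
  n <- length(x)
  stopifnot(window_len >= 1, n >= 2 * window_len)
  s_all <- stats::sd(x)
  if (s_all == 0) return(NA_real_)
  n_win <- floor(n / window_len)
  m <- matrix(x[seq_len(n_win * window_len)], nrow = window_len)
  stats::sd(colMeans(m)) / s_all
}

#' Distribution-shape statistics
#'
#' Root-mean-square, sample SD (N-1 denominator) and standardized central
#' moments of orders 3-5 (central moment of order k, computed with the 1/N
#' mean, divided by `SD^k`; order 4 is thus ordinary, non-excess kurtosis,
#' which is 3 for a Gaussian).
#'
#' @param x Numeric vector, length >= 2.
#' @return Named list: `rms`, `standard_deviation`, `moment_3`, `moment_4`,
#'   `moment_5` (moments `NA` for constant input).
#' @export
distribution_stats <- function(x) {
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  xc <- x - mean(x)
  mom <- function(k) if (s == 0) NA_real_ else mean(xc^k) / s^k
  list(rms = sqrt(mean(x^2)), standard_deviation = s,
       moment_3 = mom(3), moment_4 = mom(4), moment_5 = mom(5))
}

#' Poincare-plot dispersion (SD1 / SD2)
#'
#' From the scatter of consecutive sample pairs `(x_t, x_{t+1})`: SD1 is the
#' dispersion perpendicular to the identity line, `SD((x_{t+1} - x_t)/sqrt(2))`,
#' capturing sample-to-sample variability; SD2 is the dispersion along it,
#' `SD((x_{t+1} + x_t)/sqrt(2))`. SDs use the N-1 denominator over the N-1
#' pairs. For white noise SD1 ~ SD2 ~ SD(x); strong lag-1 autocorrelation
#' shrinks SD1 relative to SD2.
#'
#' @param x Numeric vector, length >= 3.
#' @return Named list with `sd1` and `sd2`.
#' @export
poincare_sd <- function(x) {
  stopifnot(length(x) >= 3)
  a <- x[-length(x)]
  b <- x[-1]
  list(sd1 = stats::sd((b - a) / sqrt(2)), sd2 = stats::sd((b + a) / sqrt(2)))
}

#' Welch power spectral density (rectangular window)
#'
#' Averages one-sided periodograms of 50%-overlapping rectangular-window
#' segments (default segment length `min(length(x), 1024)`).
#'
#' @param x Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param seg_len Segment length in samples.
#' @param overlap Fractional overlap between consecutive segments.
#' @return List with `freq` (Hz, 0 to Nyquist) and `psd` (power/Hz).
#' @export
welch_psd <- function(x, sample_rate, seg_len = min(length(x), 1024),
                      overlap = 0.5) {
  n <- length(x)
  stopifnot(seg_len >= 2, seg_len <= n, overlap >= 0, overlap < 1)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    p <- abs(stats::fft(seg))^2 / (sample_rate * seg_len)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double the interior bins (not DC, not Nyquist-if-present)
  interior <- 2:(nf - if (seg_len %% 2 == 0) 1 else 0)
  psd[interior] <- 2 * psd[interior]
  list(freq = (seq_len(nf) - 1) * sample_rate / seg_len, psd = psd)
}

#' Spectral band areas and edge frequencies
#'
#' From the Welch (rectangular-window) PSD: the integrated power in each of
#' `n_bands` equal divisions of `[0, Nyquist]`, its natural log, and the
#' spectral edge frequency at each requested percentile (lowest frequency at
#' which the cumulative PSD reaches that percentage of total power).
#'
#' @param x Numeric vector, length >= 64.
#' @param sample_rate Sampling rate in Hz.
#' @param n_bands Number of equal frequency bands.
#' @param edge_percents Percentiles (in percent) for edge frequencies.
#' @param seg_len Welch segment length.
#' @return Named list: `band_area` (length `n_bands`), `log_band_area`, and
#'   `edge_freq` (one per percentile). Log areas and edge frequencies are `NA`
#'   for zero-power input.
#' @export
spectral_summaries <- function(x, sample_rate, n_bands = 5,
                               edge_percents = c(5, 10, 25, 95),
                               seg_len = min(length(x), 1024)) {
  stopifnot(length(x) >= 64, n_bands >= 1)
  ps <- welch_psd(x, sample_rate, seg_len = seg_len)
  df <- ps$freq[2] - ps$freq[1]
  total <- sum(ps$psd) * df
  nyq <- sample_rate / 2
  edges <- seq(0, nyq, length.out = n_bands + 1)
  band_area <- vapply(seq_len(n_bands), function(i) {
    in_band <- ps$freq > edges[i] & ps$freq <= edges[i + 1]
    if (i == 1) in_band <- in_band | ps$freq == 0
    sum(ps$psd[in_band]) * df
  }, numeric(1))
  if (total <= 0) {
    log_band_area <- rep(NA_real_, n_bands)
    edge_freq <- rep(NA_real_, length(edge_percents))
  } else {
    log_band_area <- ifelse(band_area > 0, log(band_area), NA_real_)
    cum <- cumsum(ps$psd) / sum(ps$psd)
    edge_freq <- vapply(edge_percents, function(p) {
      ps$freq[which(cum >= p / 100)[1]]
    }, numeric(1))
  }
  list(band_area = band_area, log_band_area = log_band_area,
       edge_freq = stats::setNames(edge_freq, paste0("p", edge_percents)))
}

# Chebyshev-distance template match counts for entropy estimators.
embed_count <- function(x, m, r, include_self) {
  n <- length(x)
  nm <- n - m
  d <- matrix(0, nm, nm)
  for (k in 0:(m - 1)) {
    v <- x[(1 + k):(nm + k)]
    d <- pmax(d, abs(outer(v, v, "-")))
  }
  within_m <- d <= r
  v <- x[(1 + m):(nm + m)]
  d1 <- pmax(d, abs(outer(v, v, "-")))
  within_m1 <- d1 <= r
  if (include_self) {
    list(cm = rowSums(within_m) / nm, cm1 = rowSums(within_m1) / nm)
  } else {
    list(B = (sum(within_m) - nm) / 2, A = (sum(within_m1) - nm) / 2)
  }
}

#' Sample entropy
#'
#' `-log(A / B)` where `B` is the number of template pairs of length `m`
#' within Chebyshev tolerance `r` and `A` the number still within `r` at
#' length `m + 1`, self-matches excluded.
#'
#' @param x Numeric vector.
#' @param m Template length.
#' @param r Tolerance; defaults to `0.2 * SD(x)`.
#' @return Non-negative scalar; `NA` for constant input or when no template
#'   pairs match.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  stopifnot(length(x) > m + 2)
  if (!is.finite(r) || r <= 0) return(NA_real_)
  cnt <- embed_count(x, m, r, include_self = FALSE)
  if (cnt$B == 0 || cnt$A == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

#' Approximate entropy
#'
#' `phi_m - phi_{m+1}` with `phi_m` the mean log fraction of templates (self
#' included) within Chebyshev tolerance `r` at length `m`.
#'
#' @inheritParams sample_entropy
#' @return Scalar; `NA` for constant input.
#' @export
approx_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  stopifnot(length(x) > m + 2)
  if (!is.finite(r) || r <= 0) return(NA_real_)
  cnt <- embed_count(x, m, r, include_self = TRUE)
  mean(log(cnt$cm)) - mean(log(cnt$cm1))
}

#' Permutation entropy
#'
#' Shannon entropy (bits) of the distribution of ordinal patterns of
#' `order` consecutive (delayed) samples, optionally normalized by
#' `log2(order!)` so that 1 means all patterns equally frequent. A strictly
#' monotone series has a single pattern and entropy 0. Invariant to strictly
#' increasing transforms of `x`.
#'
#' @param x Numeric vector.
#' @param order Pattern length (>= 2).
#' @param delay Delay in samples between pattern elements.
#' @param normalized Normalize to `[0, 1]`?
#' @return Scalar entropy.
#' @export
perm_entropy <- function(x, order = 3, delay = 1, normalized = TRUE) {
  n <- length(x)
  stopifnot(order >= 2, delay >= 1, n >= (order - 1) * delay + 2)
  n_pat <- n - (order - 1) * delay
  cols <- vapply(0:(order - 1), function(j) x[(1 + j * delay):(n_pat + j * delay)],
                 numeric(n_pat))
  # Lehmer code of each row's ordinal pattern (ties broken by position)
  code <- numeric(n_pat)
  for (j in seq_len(order - 1)) {
    less <- numeric(n_pat)
    for (k in (j + 1):order) {
      less <- less + (cols[, k] < cols[, j])
    }
    code <- code * (order - j + 1) + less
  }
  p <- tabulate(code + 1, nbins = factorial(order))
  p <- p[p > 0] / n_pat
  h <- -sum(p * log2(p))
  if (normalized) h / log2(factorial(order)) else h
}

# LZ76 phrase count by exhaustive-history parsing. For the phrase starting at
# position p, the longest prefix of s[p..] that already occurs in the history
# (overlap allowed) is found by binary search over fixed-string matches; the
# phrase is that prefix plus one symbol.
lz76_phrase_count <- function(bits) {
  s <- paste(as.integer(bits), collapse = "")
  n <- nchar(s)
  p <- 1L
  count <- 0L
  while (p <= n) {
    count <- count + 1L
    lo <- 0L
    hi <- n - p + 1L   # upper bound on the matched-prefix length
    while (lo < hi) {
      mid <- lo + (hi - lo + 1L) %/% 2L
      pat <- substr(s, p, p + mid - 1L)
      hist <- substr(s, 1L, p + mid - 2L)
      if (grepl(pat, hist, fixed = TRUE)) lo <- mid else hi <- mid - 1L
    }
    p <- p + min(lo + 1L, n - p + 1L)
  }
  count
}

#' Normalized Lempel-Ziv (LZ76) complexity
#'
#' Binarizes the signal (1 where strictly above the median), counts LZ76
#' phrases `c` by exhaustive-history parsing, and returns
#' `c * log2(N) / N`. Random binary sequences approach 1; periodic sequences
#' approach 0 as N grows. Constant input returns 0 by convention (no
#' structure to parse).
#'
#' @param x Numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
lz_complexity <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  if (length(unique(x)) == 1) return(0)
  bits <- x > stats::median(x)
  lz76_phrase_count(bits) * log2(n) / n
}

#' Dispersion of local extrema
#'
#' Splits the signal into `floor(N / window_len)` non-overlapping windows and
#' summarizes the per-window extrema: the SD (N-1 denominator) and mean of
#' window maxima and minima. Spiky, outlier-prone signals give large `stdmax`.
#'
#' @param x Numeric vector with at least `2 * window_len` samples.
#' @param window_len Window length in samples.
#' @return Named list: `stdmax`, `stdmin`, `meanmax`, `meanmin`.
#' @export
local_extrema_stats <- function(x, window_len = 50) {
  n <- length(x)
  stopifnot(window_len >= 1, n >= 2 * window_len)
  n_win <- floor(n / window_len)
  m <- matrix(x[seq_len(n_win * window_len)], nrow = window_len)
  maxima <- apply(m, 2, max)
  minima <- apply(m, 2, min)
  list(stdmax = stats::sd(maxima), stdmin = stats::sd(minima),
       meanmax = mean(maxima), meanmin = mean(minima))
}

#' First zero crossing of the autocorrelation function
#'
#' Smallest lag `k >= 1` with `ac_lag(x, k) <= 0`, the standard embedding
#' delay heuristic; `NA` if the ACF stays positive through `max_lag`.
#'
#' @param x Numeric vector.
#' @param max_lag Largest lag searched (default `floor(length(x) / 2)`).
#' @return Integer lag or `NA`.
#' @export
first_zero_ac <- function(x, max_lag = floor(length(x) / 2)) {
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(NA_integer_)
  n <- length(x)
  for (k in seq_len(max_lag)) {
    if (sum(xc[1:(n - k)] * xc[(k + 1):n]) <= 0) return(k)
  }
  NA_integer_
}

#' Grassberger-Procaccia correlation-dimension estimate at a fixed scale
#'
#' Builds a time-delay embedding (delay = first zero crossing of the ACF),
#' computes the correlation sum `C(r)` over `n_scales` logarithmically spaced
#' radii spanning the range of pairwise distances, takes local slopes of
#' `log C` versus `log r` (central differences), and reports the slope at the
#' requested scale index. A noisy line-like signal gives estimates near 1;
#' i.i.d. noise fills the embedding space and gives much larger values.
#'
#' @param x Numeric vector.
#' @param n_scales Number of radii.
#' @param embed_dim Embedding dimension.
#' @param report_scale_index Index (1-based) of the radius whose local slope
#'   is returned.
#' @param delay Embedding delay in samples; `NULL` (default) uses the first
#'   zero crossing of the ACF.
#' @return Dimension estimate, or `NA` when the ACF never reaches zero, the
#'   embedding is degenerate, or the correlation sum is empty at the scale.
#' @export
box_corr_dim <- function(x, n_scales = 50, embed_dim = 5,
                         report_scale_index = 13, delay = NULL) {
  if (is.null(delay)) delay <- first_zero_ac(x)
  if (is.na(delay)) return(NA_real_)
  n_pts <- length(x) - (embed_dim - 1) * delay
  if (n_pts < 100) stop("too few samples for the requested embedding")
  emb <- vapply(0:(embed_dim - 1), function(j) x[(1 + j * delay):(n_pts + j * delay)],
                numeric(n_pts))
  dists <- as.numeric(stats::dist(emb))
  dmax <- max(dists)
  dmin <- min(dists[dists > 0])
  if (!is.finite(dmin) || dmax <= 0 || dmin >= dmax) return(NA_real_)
  radii <- exp(seq(log(dmin), log(dmax), length.out = n_scales))
  cr <- vapply(radii, function(r) mean(dists <= r), numeric(1))
  log_c <- ifelse(cr > 0, log(cr), NA_real_)
  log_r <- log(radii)
  i <- report_scale_index
  if (i < 2 || i > n_scales - 1) stop("report_scale_index out of range")
  if (is.na(log_c[i - 1]) || is.na(log_c[i + 1])) return(NA_real_)
  (log_c[i + 1] - log_c[i - 1]) / (log_r[i + 1] - log_r[i - 1])
}
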