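#' Define a named time-series feature
#'
#' @param name Unique feature identifier (hctsa-style, e.g. `"AC_30"`).
#' @param family One of `"correlation"`, `"stationarity"`, `"distribution"`,
#'   `"spectral"`, `"entropy"`, `"extrema"`, `"nonlinear"`.
#' @param fn Function `(x, sample_rate) -> scalar`; may return `NA` or
#'   `+/-Inf`, which propagate into the feature matrix.
#' @param params Named list of parameter values, recorded for provenance.
#' @return An object of class `feature_def`.
#' @export
feature_def <- function(name, family, fn, params = list()) {
  family <- match.arg(family, c("correlation", "stationarity", "distribution",
                                "spectral", "entropy", "extrema", "nonlinear"))
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  f <- list(name = name, family = family, fn = fn, params = params)
  class(f) <- "feature_def"
  f
}

#' Default feature registry
#'
#' A representative registry of univariate time-series features spanning the
#' families that discriminate wakefulness from anesthesia in fly LFP:
#' autocorrelation at lags 29-34 ms, local-mean stationarity (StatAvl250),
#' amplitude and distribution shape (rms, SD, standardized moments 3-5),
#' Poincare SD1/SD2, Welch spectral band powers and edge frequencies, sample /
#' approximate / permutation entropy and Lempel-Ziv complexity, local-extrema
#' dispersion, and a Grassberger-Procaccia correlation-dimension estimate.
#' Feature names follow the hctsa-style identifiers used in this literature.
#'
#' `SP_Summaries_welch_rect_logarea_2_1` is the log power in the lower half of
#' `[0, Nyquist]` (relative low-frequency power once compared across epochs);
#' `..._area_5_1` the power in the lowest fifth; `SP_Summaries_welch_wmax_P`
#' the spectral edge frequency at P% of cumulative power.
#'
#' @param families Optional character vector restricting the registry to the
#'   given families.
#' @param include_expensive Include the O(N^2)-per-epoch features (sample and
#'   approximate entropy, correlation dimension)? Excluding them is useful for
#'   large simulation studies.
#' @return A named list of [feature_def()] objects.
#' @export
default_feature_registry <- function(families = NULL,
                                     include_expensive = TRUE) {
  defs <- list()
  add <- function(def) defs[[def$name]] <<- def
  for (k in 29:34) {
    local({
      kk <- k
      add(feature_def(paste0("AC_", kk), "correlation",
                      function(x, sample_rate) ac_lag(x, kk),
                      params = list(lag = kk)))
    })
  }
  add(feature_def("StatAvl250", "stationarity",
                  function(x, sample_rate) statav_local(x, 250),
                  params = list(window_len = 250)))
  add(feature_def("rms", "distribution",
                  function(x, sample_rate) distribution_stats(x)$rms))
  add(feature_def("standard_deviation", "distribution",
                  function(x, sample_rate) distribution_stats(x)$standard_deviation))
  for (k in 3:5) {
    local({
      kk <- k
      add(feature_def(paste0("DN_Moments_raw_", kk), "distribution",
                      function(x, sample_rate) {
                        distribution_stats(x)[[paste0("moment_", kk)]]
                      },
                      params = list(order = kk)))
    })
  }
  add(feature_def("MD_rawHRVmeas_SD1", "distribution",
                  function(x, sample_rate) poincare_sd(x)$sd1))
  add(feature_def("MD_rawHRVmeas_SD2", "distribution",
                  function(x, sample_rate) poincare_sd(x)$sd2))
  add(feature_def("SP_Summaries_welch_rect_logarea_2_1", "spectral",
                  function(x, sample_rate) {
                    spectral_summaries(x, sample_rate, n_bands = 2)$log_band_area[1]
                  },
                  params = list(n_bands = 2, band = 1)))
  add(feature_def("SP_Summaries_welch_rect_area_5_1", "spectral",
                  function(x, sample_rate) {
                    spectral_summaries(x, sample_rate, n_bands = 5)$band_area[1]
                  },
                  params = list(n_bands = 5, band = 1)))
  for (p in c(5, 10, 25, 95)) {
    local({
      pp <- p
      add(feature_def(paste0("SP_Summaries_welch_wmax_", pp), "spectral",
                      function(x, sample_rate) {
                        spectral_summaries(x, sample_rate,
                                           edge_percents = pp)$edge_freq[[1]]
                      },
                      params = list(percent = pp)))
    })
  }
  if (include_expensive) {
    add(feature_def("EN_SampEn", "entropy",
                    function(x, sample_rate) sample_entropy(x),
                    params = list(m = 2, r = "0.2 SD")))
    add(feature_def("ApEn", "entropy",
                    function(x, sample_rate) approx_entropy(x),
                    params = list(m = 2, r = "0.2 SD")))
  }
  add(feature_def("EN_PermEn", "entropy",
                  function(x, sample_rate) perm_entropy(x, order = 3),
                  params = list(order = 3, delay = 1)))
  add(feature_def("EN_MS_LZcomplexity", "entropy",
                  function(x, sample_rate) lz_complexity(x)))
  add(feature_def("ST_LocalExtrema_n50_stdmax", "extrema",
                  function(x, sample_rate) local_extrema_stats(x, 50)$stdmax,
                  params = list(window_len = 50)))
  add(feature_def("ST_LocalExtrema_n50_stdmin", "extrema",
                  function(x, sample_rate) local_extrema_stats(x, 50)$stdmin,
                  params = list(window_len = 50)))
  if (include_expensive) {
    add(feature_def("NL_BoxCorrDim_50_ac_5_minr13", "nonlinear",
                    function(x, sample_rate) box_corr_dim(x),
                    params = list(n_scales = 50, embed_dim = 5,
                                  scale_index = 13)))
  }
  if (!is.null(families)) {
    defs <- Filter(function(d) d$family %in% families, defs)
  }
  defs
}

#' List the features in a registry
#'
#' @param registry A list of [feature_def()] objects.
#' @return Data frame with `name` and `family`.
#' @export
list_features <- function(registry = default_feature_registry()) {
  data.frame(name = vapply(registry, `[[`, character(1), "name"),
             family = vapply(registry, `[[`, character(1), "family"),
             row.names = NULL, stringsAsFactors = FALSE)
}
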