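#' Configuration for the synthetic LFP study generator
#'
#' Describes a multi-dataset, multi-fly, multi-condition recording study whose
#' signals mimic the statistical structure of fly LFP under wakefulness and
#' anesthesia/sleep: condition-dependent autocorrelation timescale (wake slower
#' than unconscious) and signal variance (wake larger), per-fly baseline
#' offsets, per-dataset batch effects (gain, additive offset, optional
#' low-pass filtering), and mains line-noise contamination.
#'
#' The wake/unconscious contrast at bipolar channel `j` is scaled by
#' `channel_effect_profile[j]`: wake-condition parameters at that channel are
#' `unconscious + profile * (wake - unconscious)`, so a profile of 0 makes the
#' two conditions statistically identical there. The default profile decays
#' linearly from 1 at channel 1 (deepest, strongest effect) to 0.25 at the
#' shallowest channel.
#'
#' @param datasets Named integer vector: number of flies per dataset label.
#' @param n_epochs_per_condition Epochs per fly per condition (equal across
#'   conditions, which fixes chance classification at 50%).
#' @param epoch_seconds Epoch duration in seconds; `epoch_seconds *
#'   sample_rate` must be a whole number of samples.
#' @param sample_rate Sampling rate in Hz.
#' @param n_electrodes Electrodes per fly, ordered by depth (1 = deepest);
#'   bipolar re-referencing yields `n_electrodes - 1` channels.
#' @param wake_conditions,unconscious_conditions Character vectors of condition
#'   labels drawn with wake-like and unconscious-like parameters respectively.
#' @param tau_wake,tau_unconscious AR(1) autocorrelation time constants in ms.
#' @param sigma_wake,sigma_unconscious Stationary signal SD (arbitrary volts).
#' @param fly_offset_sd SD of the per-fly additive baseline (constant across
#'   that fly's epochs, conditions and electrodes).
#' @param batch_gain Named numeric per dataset: multiplicative gain (default 1).
#' @param batch_offset Named numeric per dataset: additive voltage shift
#'   (default 0).
#' @param batch_lowpass_hz Named numeric per dataset: low-pass cutoff in Hz,
#'   `NA` for none (default). Mimics a dataset recorded through a narrower
#'   hardware filter.
#' @param line_noise_hz Mains frequency in Hz (default 50).
#' @param line_noise_amp Amplitude of the mains sinusoid added to each
#'   electrode epoch with random phase (0 disables).
#' @param channel_effect_profile Numeric vector of length `n_electrodes - 1`
#'   of per-channel effect multipliers in `[0, 1]`; `NULL` for the default
#'   decaying profile.
#' @param seed Integer master seed; every fly gets an independent stream
#'   derived from it, so adding flies or datasets never perturbs the signals
#'   of existing ones.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(datasets = c(discovery = 13),
                         n_epochs_per_condition = 8,
                         epoch_seconds = 2.25,
                         sample_rate = 1000,
                         n_electrodes = 16,
                         wake_conditions = "wake",
                         unconscious_conditions = "anesthesia",
                         tau_wake = 30,
                         tau_unconscious = 8,
                         sigma_wake = 1.5,
                         sigma_unconscious = 1,
                         fly_offset_sd = 0.5,
                         batch_gain = NULL,
                         batch_offset = NULL,
                         batch_lowpass_hz = NULL,
                         line_noise_hz = 50,
                         line_noise_amp = 0.5,
                         channel_effect_profile = NULL,
                         seed = 1L) {
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    stop("datasets must be a named vector of fly counts")
  }
  stopifnot(all(datasets >= 1), n_epochs_per_condition >= 1,
            epoch_seconds > 0, sample_rate > 0, n_electrodes >= 2,
            tau_wake > 0, tau_unconscious > 0,
            sigma_wake > 0, sigma_unconscious > 0,
            fly_offset_sd >= 0, line_noise_hz > 0, line_noise_amp >= 0)
  n_samp <- epoch_seconds * sample_rate
  if (abs(n_samp - round(n_samp)) > 1e-8) {
    stop("epoch_seconds * sample_rate must be an integer sample count")
  }
  n_channels <- n_electrodes - 1
  if (is.null(channel_effect_profile)) {
    channel_effect_profile <- seq(1, 0.25, length.out = n_channels)
  }
  if (length(channel_effect_profile) != n_channels) {
    stop("channel_effect_profile must have length n_electrodes - 1")
  }
  if (any(channel_effect_profile < 0)) {
    stop("channel_effect_profile must be non-negative")
  }
  ds <- names(datasets)
  fill <- function(x, default) {
    out <- stats::setNames(rep(default, length(ds)), ds)
    if (!is.null(x)) {
      unknown <- setdiff(names(x), ds)
      if (length(unknown) > 0) stop("unknown dataset in batch parameter: ",
                                    paste(unknown, collapse = ", "))
      out[names(x)] <- x
    }
    out
  }
  cfg <- list(datasets = datasets,
              n_epochs_per_condition = as.integer(n_epochs_per_condition),
              epoch_seconds = epoch_seconds,
              sample_rate = sample_rate,
              n_electrodes = as.integer(n_electrodes),
              wake_conditions = wake_conditions,
              unconscious_conditions = unconscious_conditions,
              tau_wake = tau_wake, tau_unconscious = tau_unconscious,
              sigma_wake = sigma_wake, sigma_unconscious = sigma_unconscious,
              fly_offset_sd = fly_offset_sd,
              batch_gain = fill(batch_gain, 1),
              batch_offset = fill(batch_offset, 0),
              batch_lowpass_hz = fill(batch_lowpass_hz, NA_real_),
              line_noise_hz = line_noise_hz,
              line_noise_amp = line_noise_amp,
              channel_effect_profile = channel_effect_profile,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Generate one stationary AR(1) epoch
#'
#' Draws a discrete Ornstein-Uhlenbeck (first-order autoregressive) sequence
#' with coefficient `phi = exp(-dt / tau_ms)` where `dt = 1000 / sample_rate`
#' ms, innovations scaled so the stationary SD equals `sigma`, and a
#' stationary initial state. The lag-k autocorrelation is `phi^k`, so
#' `tau_ms = 30` at 1000 Hz gives autocorrelation `exp(-1) ~ 0.368` at lag 30.
#'
#' @param tau_ms Autocorrelation time constant in milliseconds (> 0).
#' @param sigma Stationary standard deviation (> 0).
#' @param n_samples Number of samples (>= 2).
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric vector of length `n_samples`, mean zero in expectation.
#' @export
generate_epoch <- function(tau_ms, sigma, n_samples, sample_rate = 1000) {
  if (!is.numeric(tau_ms) || tau_ms <= 0) stop("tau_ms must be positive")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  stopifnot(n_samples >= 2, sample_rate > 0)
  phi <- exp(-(1000 / sample_rate) / tau_ms)
  innov_sd <- sigma * sqrt(1 - phi^2)
  x0 <- stats::rnorm(1, 0, sigma)
  e <- stats::rnorm(n_samples, 0, innov_sd)
  as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
}

# Wake-condition AR(1) parameters at one channel: the wake/unconscious
# contrast is scaled by the channel's effect multiplier.
channel_condition_params <- function(cfg, channel, wake_like) {
  p <- cfg$channel_effect_profile[channel]
  if (wake_like) {
    list(tau = cfg$tau_unconscious + p * (cfg$tau_wake - cfg$tau_unconscious),
         sigma = cfg$sigma_unconscious + p * (cfg$sigma_wake - cfg$sigma_unconscious))
  } else {
    list(tau = cfg$tau_unconscious, sigma = cfg$sigma_unconscious)
  }
}

#' Generate a full synthetic study
#'
#' Simulates every dataset, fly, condition and electrode of the configured
#' study and returns the raw (pre-preprocessing) electrode epochs. Electrode
#' signals are constructed as partial sums of independent latent per-channel
#' AR(1) processes plus a shared reference process, so that adjacent-electrode
#' subtraction recovers exactly the latent channel signals carrying the
#' configured per-channel condition effect. Per-fly additive baselines,
#' per-dataset gain / offset / low-pass batch effects, and a mains sinusoid
#' with random phase per (epoch, electrode) are then applied.
#'
#' Each fly's randomness comes from an independent stream derived from the
#' master seed, so the output is fully deterministic given the configuration
#' and unchanged for existing flies when more flies or datasets are appended.
#'
#' @param config A [synth_config()].
#' @return An [epoch_set()] of raw electrode signals (`signal_type =
#'   "electrode"`), with the configuration (including the ground-truth effect
#'   profile and direction) attached as provenance.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n_samp <- as.integer(round(cfg$epoch_seconds * cfg$sample_rate))
  n_ep <- cfg$n_epochs_per_condition
  n_el <- cfg$n_electrodes
  n_ch <- n_el - 1
  conditions <- c(cfg$wake_conditions, cfg$unconscious_conditions)
  wake_like <- conditions %in% cfg$wake_conditions
  total_len <- n_ep * n_samp

  sample_list <- list()
  meta_list <- list()
  fly_counter <- 0L
  for (d in names(cfg$datasets)) {
    gain <- cfg$batch_gain[[d]]
    offset <- cfg$batch_offset[[d]]
    lp <- cfg$batch_lowpass_hz[[d]]
    for (f in seq_len(cfg$datasets[[d]])) {
      fly_counter <- fly_counter + 1L
      fly_seed <- (cfg$seed + 104729L * fly_counter) %% 2147483647L
      fly_id <- sprintf("fly%02d", f)
      rec <- withr::with_seed(fly_seed, {
        fly_offset <- stats::rnorm(1, 0, cfg$fly_offset_sd)
        out <- list()
        for (ci in seq_along(conditions)) {
          # latent channel processes, continuous across the fly's epochs
          latent <- matrix(0, n_ch, total_len)
          for (ch in seq_len(n_ch)) {
            pars <- channel_condition_params(cfg, ch, wake_like[ci])
            latent[ch, ] <- generate_epoch(pars$tau, pars$sigma, total_len,
                                           cfg$sample_rate)
          }
          ref <- generate_epoch(cfg$tau_unconscious, cfg$sigma_unconscious,
                                total_len, cfg$sample_rate)
          # electrode i = reference + sum of latent channels i..n_ch
          electrodes <- matrix(0, n_el, total_len)
          electrodes[n_el, ] <- ref
          for (i in rev(seq_len(n_ch))) {
            electrodes[i, ] <- electrodes[i + 1, ] + latent[i, ]
          }
          electrodes <- gain * (electrodes + fly_offset) + offset
          if (!is.na(lp)) {
            bf <- signal::butter(4, lp / (cfg$sample_rate / 2), type = "low")
            for (i in seq_len(n_el)) {
              electrodes[i, ] <- signal::filtfilt(bf, electrodes[i, ])
            }
          }
          if (cfg$line_noise_amp > 0) {
            t_s <- (seq_len(n_samp) - 1) / cfg$sample_rate
            phases <- matrix(stats::runif(n_ep * n_el, 0, 2 * pi), n_ep, n_el)
          }
          # segment into epochs, one record per (epoch, electrode)
          cond_samples <- matrix(0, n_ep * n_el, n_samp)
          r <- 0L
          for (ep in seq_len(n_ep)) {
            idx <- ((ep - 1) * n_samp + 1):(ep * n_samp)
            for (i in seq_len(n_el)) {
              r <- r + 1L
              v <- electrodes[i, idx]
              if (cfg$line_noise_amp > 0) {
                v <- v + cfg$line_noise_amp *
                  sin(2 * pi * cfg$line_noise_hz * t_s + phases[ep, i])
              }
              cond_samples[r, ] <- v
            }
          }
          out[[conditions[ci]]] <- cond_samples
        }
        out
      })
      for (ci in seq_along(conditions)) {
        sample_list[[length(sample_list) + 1L]] <- rec[[conditions[ci]]]
        meta_list[[length(meta_list) + 1L]] <- data.frame(
          dataset = d, fly = fly_id, condition = conditions[ci],
          channel = rep(seq_len(n_el), times = n_ep),
          epoch = rep(seq_len(n_ep), each = n_el),
          stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, sample_list)
  meta <- do.call(rbind, meta_list)
  epoch_set(samples, meta, cfg$sample_rate, signal_type = "electrode",
            provenance = cfg)
}
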