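test_that("generate_epoch matches AR(1) closed-form autocorrelation and variance", {
  withr::with_seed(11, {
    # near-white-noise limit: tiny tau gives lag-1 autocorrelation near 0
    x <- generate_epoch(tau_ms = 0.05, sigma = 1, n_samples = 50000)
    expect_lt(abs(ac_lag(x, 1)), 0.02)

    # tau = 30 ms at 1000 Hz: AC at lag 30 is exp(-1) (the per-epoch
    # estimator carries a small negative finite-sample bias, within the band)
    ac30 <- replicate(500, ac_lag(generate_epoch(30, 1, 2250), 30))
    expect_lt(abs(mean(ac30) - exp(-1)), 0.05)

    # stationary SD recovered from pooled samples
    pooled <- generate_epoch(tau_ms = 10, sigma = 2, n_samples = 1e6)
    expect_gt(sd(pooled), 1.9)
    expect_lt(sd(pooled), 2.1)
  })
})

test_that("generate_epoch rejects non-positive parameters", {
  expect_error(generate_epoch(0, 1, 100), "tau_ms")
  expect_error(generate_epoch(-5, 1, 100), "tau_ms")
  expect_error(generate_epoch(30, 0, 100), "sigma")
})

test_that("generate_study has the configured record structure", {
  cfg <- synth_config(datasets = c(discovery = 13), seed = 5,
                      line_noise_amp = 0)
  es <- generate_study(cfg)
  m <- es$meta
  # 13 flies x 2 conditions x 8 epochs = 208 records per electrode
  per_electrode <- table(m$channel)
  expect_equal(length(per_electrode), 16)
  expect_true(all(per_electrode == 208))
  expect_equal(ncol(es$samples), 2250)
  expect_s3_class(validate_epoch_set(es), "epoch_set")
})

test_that("zero offsets and unit gain give mean-zero pooled signal", {
  cfg <- synth_config(datasets = c(d = 4), n_electrodes = 3,
                      fly_offset_sd = 0, line_noise_amp = 0, seed = 2)
  es <- generate_study(cfg)
  v <- as.numeric(es$samples)
  se <- sd(v) / sqrt(length(v))  # correlated samples make this generous
  expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v) / 100))
})

test_that("identical seeds give byte-identical studies; added flies leave existing ones unchanged", {
  cfg <- synth_config(datasets = c(d = 3), n_electrodes = 3, seed = 42)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$meta, b$meta)

  cfg_more <- synth_config(datasets = c(d = 5), n_electrodes = 3, seed = 42)
  c_ <- generate_study(cfg_more)
  keep <- c_$meta$fly %in% c("fly01", "fly02", "fly03")
  expect_identical(c_$samples[keep, ], a$samples)
})

test_that("zero-effect channels carry no condition contrast", {
  cfg <- synth_config(datasets = c(d = 8), n_electrodes = 3,
                      channel_effect_profile = c(1, 0),
                      fly_offset_sd = 0, line_noise_amp = 0, seed = 9)
  pp <- preprocess_epochs(generate_study(cfg))
  m <- pp$meta
  sds <- apply(pp$samples, 1, sd)
  # strong-effect channel: wake clearly larger SD than anesthesia
  ch1_w <- mean(sds[m$channel == 1 & m$condition == "wake"])
  ch1_a <- mean(sds[m$channel == 1 & m$condition == "anesthesia"])
  expect_gt(ch1_w / ch1_a, 1.2)
  # zero-effect channel: ratio near 1
  ch2_w <- mean(sds[m$channel == 2 & m$condition == "wake"])
  ch2_a <- mean(sds[m$channel == 2 & m$condition == "anesthesia"])
  expect_lt(abs(ch2_w / ch2_a - 1), 0.1)
})

test_that("config validation enforces the documented invariants", {
  expect_error(synth_config(datasets = c(5)), "named")
  expect_error(synth_config(epoch_seconds = 2.2501), "integer sample count")
  expect_error(synth_config(tau_wake = -1))
  expect_error(synth_config(channel_effect_profile = c(1, 1)), "length")
  expect_error(synth_config(batch_gain = c(nope = 2)), "unknown dataset")
})

test_that("epoch sets round-trip through the plain-text container", {
  cfg <- synth_config(datasets = c(d = 2), n_electrodes = 3,
                      n_epochs_per_condition = 2, seed = 3)
  es <- generate_study(cfg)
  stem <- file.path(withr::local_tempdir(), "es")
  write_epoch_set(es, stem)
  back <- read_epoch_set(stem)
  expect_equal(back$samples, es$samples, tolerance = 1e-12)
  expect_equal(back$meta, es$meta)
  expect_equal(back$sample_rate, es$sample_rate)
})
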