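test_that("ac_lag implements the biased estimator", {
  expect_equal(ac_lag(rnorm(50), 0), 1)
  alt <- rep(c(1, -1), 5)
  expect_equal(ac_lag(alt, 1), -0.9)          # -(N-1)/N for alternating signs
  withr::with_seed(5, {
    x <- as.numeric(arima.sim(list(ar = 0.8), 200))
    for (k in c(1, 3, 17)) expect_equal(ac_lag(x, k), brute_force_ac(x, k))
  })
  expect_true(is.na(ac_lag(rep(2, 100), 5)))
  # invariant to affine transforms
  withr::with_seed(6, x <- rnorm(500))
  expect_equal(ac_lag(3 * x - 7, 4), ac_lag(x, 4))
})

test_that("statav_local measures mean-stationarity", {
  expect_equal(statav_local(c(0, 0, 2, 2), 2), sqrt(6) / 2)
  withr::with_seed(8, {
    iid <- rnorm(50000)
    expect_lt(statav_local(iid, 250), 0.15)   # ~ window_len^(-1/2) scale
    drift <- iid + seq(0, 20, length.out = 50000)
    expect_gt(statav_local(drift, 250), statav_local(iid, 250))
  })
  expect_true(is.na(statav_local(rep(1, 1000), 250)))
})

test_that("distribution statistics follow the stated conventions", {
  expect_equal(distribution_stats(c(3, -3))$rms, 3)
  expect_equal(distribution_stats(c(1, 2, 3))$standard_deviation, 1)
  withr::with_seed(9, g <- rnorm(2e5))
  expect_lt(abs(distribution_stats(g)$moment_4 - 3), 0.1)  # Gaussian kurtosis
  expect_lt(abs(distribution_stats(g)$moment_3), 0.05)
  expect_true(is.na(distribution_stats(rep(1, 10))$moment_4))
})

test_that("Poincare SD1/SD2 match direct computation", {
  expect_equal(poincare_sd(rep(5, 20)), list(sd1 = 0, sd2 = 0))
  x <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  d <- (x[-1] - x[-10]) / sqrt(2)
  s <- (x[-1] + x[-10]) / sqrt(2)
  expect_equal(poincare_sd(x), list(sd1 = sd(d), sd2 = sd(s)))
  withr::with_seed(10, iid <- rnorm(1e5, sd = 2))
  ps <- poincare_sd(iid)
  expect_lt(abs(ps$sd1 - 2), 0.05)
  expect_lt(abs(ps$sd2 - 2), 0.05)
})

test_that("spectral summaries concentrate, scale and locate power correctly", {
  t_s <- (0:4095) / 1000
  tone <- sin(2 * pi * 10 * t_s)
  ss <- spectral_summaries(tone, 1000, n_bands = 2)
  expect_gt(ss$band_area[1] / sum(ss$band_area), 0.99)

  withr::with_seed(12, wn <- rnorm(2^14))
  edge50 <- spectral_summaries(wn, 1000, edge_percents = 50)$edge_freq[[1]]
  expect_lt(abs(edge50 - 250) / 250, 0.1)

  s1 <- spectral_summaries(wn, 1000, n_bands = 5)
  s2 <- spectral_summaries(2 * wn, 1000, n_bands = 5)
  expect_equal(s2$band_area, 4 * s1$band_area, tolerance = 1e-10)
  expect_equal(s2$log_band_area, s1$log_band_area + log(4), tolerance = 1e-10)
  expect_equal(s2$edge_freq, s1$edge_freq)

  zz <- spectral_summaries(rep(0, 1000), 1000, n_bands = 2)
  expect_true(all(is.na(zz$log_band_area)))
  expect_true(all(is.na(zz$edge_freq)))
})

test_that("entropy features agree with independent oracles and conventions", {
  withr::with_seed(14, x <- as.numeric(arima.sim(list(ar = 0.9), 300)))
  r <- 0.2 * sd(x)
  skip_if_not_installed("pracma")
  expect_equal(sample_entropy(x, 2, r),
               pracma::sample_entropy(x, edim = 2, r = r, tau = 1),
               tolerance = 1e-10)
  expect_equal(approx_entropy(x, 2, r),
               pracma::approx_entropy(x, edim = 2, r = r),
               tolerance = 0.02)
  expect_true(is.na(sample_entropy(rep(1, 100))))
  expect_true(is.na(approx_entropy(rep(1, 100))))
})

test_that("permutation entropy is 0 for monotone series and invariant to monotone maps", {
  expect_equal(perm_entropy(1:100, order = 3), 0)
  withr::with_seed(15, x <- rnorm(2000))
  expect_lt(abs(perm_entropy(x, 3) - 1), 0.01)   # iid: all patterns equal
  expect_equal(perm_entropy(exp(x), 3), perm_entropy(x, 3))
})

test_that("LZ76 complexity separates periodic from random sequences", {
  # periodic: phrase count stays bounded, normalized complexity shrinks with N
  per_short <- rep(c(0, 1, 1), 100)
  per_long <- rep(c(0, 1, 1), 700)
  expect_gt(lz_complexity(per_short), lz_complexity(per_long))
  expect_lt(lz_complexity(per_long), 0.1)
  # continuous noise binarized at its median is a fair-coin sequence
  withr::with_seed(16, coin_like <- rnorm(4000))
  expect_lt(abs(lz_complexity(coin_like) - 1), 0.15)  # LZ76 asymptotic
  expect_equal(lz_complexity(rep(3, 100)), 0)  # constant input, by convention
  expect_equal(perm_entropy(rep(3, 100)), 0)
})

test_that("local extrema dispersion matches brute-force enumeration", {
  expect_equal(local_extrema_stats(rep(2, 200), 50)$stdmax, 0)
  withr::with_seed(17, x <- rnorm(200))
  out <- local_extrema_stats(x, 50)
  wins <- split(x, rep(1:4, each = 50))
  expect_equal(out$stdmax, sd(sapply(wins, max)))
  expect_equal(out$stdmin, sd(sapply(wins, min)))
  expect_equal(out$meanmax, mean(sapply(wins, max)))
  # a single spike inflates stdmax; removing it lowers the statistic
  spiked <- x; spiked[25] <- 40
  expect_gt(local_extrema_stats(spiked, 50)$stdmax, out$stdmax)
})

test_that("correlation-dimension estimate recovers known geometries", {
  withr::with_seed(18, {
    ramp <- seq(0, 1, length.out = 2000) + rnorm(2000, sd = 1e-6)
    d_line <- box_corr_dim(ramp, delay = 3)
    expect_lt(abs(d_line - 1), 0.3)

    unif <- runif(2000)
    expect_gt(box_corr_dim(unif), 2)

    sine <- sin(2 * pi * (1:3000) / 90) + rnorm(3000, sd = 0.01)
    expect_true(is.finite(box_corr_dim(sine, delay = 5)))
    expect_true(is.finite(box_corr_dim(sine, delay = 11)))
  })
  # ACF that stays positive within the searched lags yields a missing delay,
  # which propagates through the dimension estimate
  expect_true(is.na(first_zero_ac(1:60, max_lag = 10)))
  expect_true(is.na(box_corr_dim(rnorm(600), delay = NA)))
})
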