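test_that("effect-direction labels follow the median rule with -1 on ties", {
  grid <- expand.grid(fly = c("fly01", "fly02"),
                      condition = c("wake", "anesthesia"), epoch = 1:4,
                      stringsAsFactors = FALSE)
  grid$dataset <- "d"
  grid$channel <- 1
  grid$up <- ifelse(grid$condition == "wake", 2, 1) + seq_len(nrow(grid)) * 1e-3
  grid$down <- -grid$up
  grid$flat <- rep(c(1, 2), nrow(grid) / 2)   # identical medians in both classes
  fm <- make_fm(grid, c("up", "down", "flat"))
  lab <- effect_direction_labels(fm)
  expect_equal(lab$label[lab$feature == "up"], 1)
  expect_equal(lab$label[lab$feature == "down"], -1)
  expect_equal(lab$label[lab$feature == "flat"], -1)  # literal "otherwise" rule
  expect_true(lab$degenerate[lab$feature == "flat"])
})

test_that("consistency hits its boundary values and hand-computed cases", {
  # perfect same-direction separation in every fly
  w <- list(fly01 = c(5, 6, 7), fly02 = c(9, 10))
  u <- list(fly01 = c(1, 2), fly02 = c(3, 4))
  expect_equal(within_fly_consistency(w, u, 1), 1)
  # perfectly reversed relative to the label
  expect_equal(within_fly_consistency(w, u, -1), 0)
  # hand-computed: wake 2 -> 1/2 of {1, 2.5} below; wake 3 -> both below
  expect_equal(within_fly_consistency(list(f = c(2, 3)),
                                      list(f = c(1, 2.5)), 1), 0.75)
  # ties count as not below
  expect_equal(within_fly_consistency(list(f = 2), list(f = c(2, 2)), 1), 0)
  # a fly missing one class is excluded
  expect_equal(within_fly_consistency(list(a = 5, b = 5),
                                      list(a = c(1, 9)), 1), 0.5)
})

test_that("consistency equals brute-force pair enumeration on random small instances", {
  withr::with_seed(40, {
    for (i in 1:40) {
      n_flies <- sample(1:4, 1)
      w <- u <- list()
      for (f in seq_len(n_flies)) {
        id <- sprintf("fly%02d", f)
        w[[id]] <- round(rnorm(sample(1:6, 1)), 2)   # rounding induces ties
        u[[id]] <- round(rnorm(sample(1:6, 1)), 2)
      }
      label <- sample(c(-1, 1), 1)
      expect_equal(within_fly_consistency(w, u, label),
                   brute_force_consistency(w, u, label))
    }
  })
})

test_that("consistency is rank-based: invariant to increasing per-fly transforms", {
  withr::with_seed(41, {
    w <- list(a = rnorm(8, 1), b = rnorm(8, 1))
    u <- list(a = rnorm(8), b = rnorm(8))
    base <- within_fly_consistency(w, u, 1)
    # different strictly increasing transform (and offset) per fly
    w2 <- list(a = exp(w$a), b = 100 + 3 * w$b)
    u2 <- list(a = exp(u$a), b = 100 + 3 * u$b)
    expect_equal(within_fly_consistency(w2, u2, 1), base)
  })
})

test_that("fly-level offsets destroy accuracy but spare consistency", {
  withr::with_seed(42, {
    flies <- sprintf("fly%02d", 1:6)
    offs <- setNames(seq(0, 100, length.out = 6), flies)
    w <- u <- list()
    grid <- list()
    for (f in flies) {
      w[[f]] <- rnorm(8, 2) + offs[f]     # within-fly: wake above anesthesia
      u[[f]] <- rnorm(8, 0) + offs[f]
    }
    expect_gt(within_fly_consistency(w, u, 1), 0.85)
    # across-fly classifier at the pooled medians is near chance
    clf <- fit_classifier(unlist(w), unlist(u))
    acc <- predict_accuracy(clf, unlist(w), unlist(u))
    expect_lt(acc, 0.7)
  })
})

test_that("consistency permutation null is centered and respects achievable proportions", {
  counts <- data.frame(n_wake = rep(8, 13), n_unconscious = rep(8, 13))
  null <- permutation_null_consistency(counts, n_reps = 7702, seed = 43)
  expect_lt(abs(mean(null) - 0.5), 0.005)

  tiny <- permutation_null_consistency(
    data.frame(n_wake = 1, n_unconscious = 1), n_reps = 2000, seed = 44)
  expect_true(all(tiny %in% c(0, 1)))
  expect_lt(abs(mean(tiny) - 0.5), 0.05)

  big <- permutation_null_consistency(
    data.frame(n_wake = rep(8, 40), n_unconscious = rep(8, 40)),
    n_reps = 2000, seed = 45)
  expect_lt(sd(big), sd(null))
})

test_that("consistency_results scores every labeled pair with p-values and FDR flags", {
  grid <- expand.grid(fly = sprintf("fly%02d", 1:5),
                      condition = c("wake", "anesthesia"), epoch = 1:8,
                      stringsAsFactors = FALSE)
  grid$dataset <- "ev"
  grid$channel <- 1
  withr::with_seed(46, {
    grid$good <- ifelse(grid$condition == "wake", rnorm(nrow(grid), 3),
                        rnorm(nrow(grid)))
    grid$junk <- rnorm(nrow(grid))
  })
  fm <- make_fm(grid, c("good", "junk"))
  labels <- data.frame(feature = c("good", "junk"), channel = 1,
                       label = 1, degenerate = FALSE)
  res <- consistency_results(labels, fm, n_reps = 2000, seed = 47)
  expect_equal(res$metric, rep("consistency", 2))
  g <- res[res$feature == "good", ]
  expect_gt(g$value, 0.9)
  expect_true(g$fdr_significant)
  j <- res[res$feature == "junk", ]
  expect_lt(abs(j$value - 0.5), 0.25)
  expect_false(j$fdr_significant)
})
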