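test_that("nearest-median classifier fits threshold and direction from class medians", {
  clf <- fit_classifier(c(1, 1, 1), c(0, 0, 0))
  expect_equal(clf$threshold, 0.5)
  expect_equal(clf$direction, 1)

  clf2 <- fit_classifier(c(0, 0, 0), c(1, 1, 1))
  expect_equal(clf2$threshold, 0.5)
  expect_equal(clf2$direction, -1)

  # infinities participate as order statistics
  clf3 <- fit_classifier(c(1, 2, Inf), c(0, 0, 1))
  expect_equal(clf3$threshold, 1)
  expect_equal(clf3$direction, 1)

  # equal medians: degenerate, tie direction +1
  clf4 <- fit_classifier(c(1, 2, 3), c(0, 2, 9))
  expect_true(clf4$degenerate)
  expect_equal(clf4$direction, 1)

  expect_error(fit_classifier(c(NA, NA), c(1, 2)), "non-missing")
})

test_that("accuracy pools both conditions with ties going to unconscious", {
  clf <- fit_classifier(c(1, 1), c(0, 0))
  expect_equal(predict_accuracy(clf, c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(predict_accuracy(clf, c(0.1, 0.2), c(0.9, 0.8)), 0)
  expect_equal(predict_accuracy(clf, c(0.4, 0.6), c(0.4, 0.6)), 0.5)
  # value exactly on the threshold is classified unconscious
  expect_equal(predict_accuracy(clf, c(0.5), c(0.5)), 0.5)
})

test_that("accuracy is invariant under strictly increasing transforms of values and threshold", {
  withr::with_seed(30, {
    w <- rnorm(20, 1)
    u <- rnorm(20)
    clf <- fit_classifier(w, u)
    g <- function(v) exp(v)          # strictly increasing
    clf_g <- fit_classifier(g(w), g(u))
    # same direction, and identical accuracy on transformed test values
    te_w <- rnorm(10, 1)
    te_u <- rnorm(10)
    expect_equal(clf_g$direction, clf$direction)
    expect_equal(predict_accuracy(clf_g, g(te_w), g(te_u)),
                 predict_accuracy(structure(list(threshold = g(clf$threshold),
                                                 direction = clf$direction),
                                            class = "median_classifier"),
                                  g(te_w), g(te_u)))
  })
})

test_that("leave-one-fly-out runs one fold per fly and detects separability", {
  grid <- expand.grid(fly = sprintf("fly%02d", 1:13),
                      condition = c("wake", "anesthesia"), epoch = 1:8,
                      stringsAsFactors = FALSE)
  grid$dataset <- "disc"
  grid$channel <- 1
  withr::with_seed(31, {
    # separable: wake always above anesthesia
    grid$sep <- ifelse(grid$condition == "wake", rnorm(nrow(grid), 5),
                       rnorm(nrow(grid)))
    # fly-specific constant: perfectly informative within training folds,
    # uninformative for a held-out fly
    fly_level <- setNames(rnorm(13, sd = 10), sprintf("fly%02d", 1:13))
    grid$flyconst <- fly_level[grid$fly]
  })
  fm <- make_fm(grid, c("sep", "flyconst"))
  cv <- lofo_cross_validate(fm)
  expect_equal(unique(cv$n_folds), 13)
  expect_equal(cv$mean_accuracy[cv$feature == "sep"], 1)
  expect_lt(abs(cv$mean_accuracy[cv$feature == "flyconst"] - 0.5), 0.25)
})

test_that("condition-pair evaluation crosses wake-like with unconscious-like states", {
  grid <- expand.grid(fly = c("fly01", "fly02"),
                      condition = c("wakeA", "wakeB", "wakeC", "isoA", "isoB"),
                      epoch = 1:4, stringsAsFactors = FALSE)
  grid$dataset <- "md"
  grid$channel <- 1
  withr::with_seed(32, {
    grid$f <- ifelse(grepl("wake", grid$condition), rnorm(nrow(grid), 3),
                     rnorm(nrow(grid)))
  })
  fm <- make_fm(grid, "f")
  clfs <- data.frame(feature = "f", channel = 1, threshold = 1.5,
                     direction = 1, degenerate = FALSE)
  res <- evaluate_condition_pairs(clfs, fm,
                                  wake_conditions = c("wakeA", "wakeB", "wakeC"),
                                  unconscious_conditions = c("isoA", "isoB"))
  expect_equal(nrow(res), 6)     # 3 wake-like x 2 unconscious-like
  expect_true(all(res$n_wake == res$n_unconscious))

  single <- evaluate_condition_pairs(clfs, fm, wake_conditions = "wakeA",
                                     unconscious_conditions = "isoB")
  expect_equal(nrow(single), 1)

  empty <- evaluate_condition_pairs(clfs, fm, wake_conditions = "nope",
                                    unconscious_conditions = "isoA")
  expect_equal(nrow(empty), 0)
})

test_that("batch normalization maps evaluation moments onto discovery moments", {
  withr::with_seed(33, {
    disc <- rnorm(100, 2, 3)
    ev <- rnorm(80, 2, 3)
    # identical distributions: near-identity map
    out <- batch_normalize(ev, mean(ev), sd(ev), mean(disc), sd(disc))
    expect_equal(mean(out), mean(disc), tolerance = 1e-10)
    expect_equal(sd(out), sd(disc), tolerance = 1e-10)
    # pure shift exactly removed
    shifted <- disc + 42
    back <- batch_normalize(shifted, mean(shifted), sd(shifted),
                            mean(disc), sd(disc))
    expect_equal(back, disc)
    # infinities pass through
    with_inf <- c(ev, Inf, -Inf)
    fin <- with_inf[is.finite(with_inf)]
    out_inf <- batch_normalize(with_inf, mean(fin), sd(fin),
                               mean(disc), sd(disc))
    expect_equal(out_inf[81:82], c(Inf, -Inf))
  })
})

test_that("random-classification null is Binomial(n, 1/2)/n with add-one p-values", {
  null11 <- permutation_null_accuracy(1, 1, n_reps = 4000, seed = 34)
  tab <- table(null11) / 4000
  expect_equal(sort(unique(null11)), c(0, 0.5, 1))
  expect_lt(abs(tab[["0"]] - 0.25), 0.03)
  expect_lt(abs(tab[["0.5"]] - 0.5), 0.03)

  null <- permutation_null_accuracy(104, 104, n_reps = 7702, seed = 35)
  expect_lt(abs(mean(null) - 0.5), 0.005)
  # accuracy 1.0 beats every null draw: p is the add-one floor
  expect_equal(permutation_p_value(1.0, null), 1 / 7703)
  expect_identical(null, permutation_null_accuracy(104, 104, 7702, seed = 35))
})

test_that("per-channel FDR equals step-up enumeration", {
  # step-up on {0.01, 0.02, 0.04, 0.9}: 0.04 > 3/4 * 0.05, so only two pass
  p <- c(0.01, 0.02, 0.04, 0.9)
  out <- fdr_correct(p, q = 0.05)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$threshold, 0.02)
  expect_equal(fdr_correct(rep(1, 6), 0.05)$significant, rep(FALSE, 6))
  expect_true(fdr_correct(0.01, 0.05)$significant)

  withr::with_seed(36, {
    for (i in 1:25) {
      p <- runif(sample(1:10, 1))^sample(1:3, 1)
      expect_equal(fdr_correct(p, 0.05)$significant, bh_step_up(p, 0.05))
    }
  })
})
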