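# Small random feature sets keep these unit tests fast; the end-to-end
# synthetic-cohort experiments live in the acceptance suite.

make_toy_features <- function(n = 12, db = 20, dc = 10, signal = 0,
                              seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  betti <- matrix(rnorm(n * db), n, db) + signal * y
  conn <- matrix(rnorm(n * dc), n, dc) + signal * y
  list(betti = betti, conn = conn, y = y)
}

test_that("inference is deterministic and well-defined on zero inputs", {
  tf <- make_toy_features()
  cfg <- bmh_net_config(backbone_hidden = 8, epochs = 5, seed = 3)
  fit <- bmh_net(tf$betti, tf$conn, tf$y, cfg)
  s1 <- predict(fit, list(betti = tf$betti, conn = tf$conn))
  s2 <- predict(fit, list(betti = tf$betti, conn = tf$conn))
  expect_identical(s1, s2)
  z <- predict(fit, list(betti = matrix(0, 2, 20), conn = matrix(0, 2, 10)))
  expect_true(all(is.finite(z) & z > 0 & z < 1))
  expect_equal(z[1], z[2])
})

test_that("shape mismatches raise errors naming the offending input", {
  tf <- make_toy_features()
  fit <- bmh_net(tf$betti, tf$conn, tf$y,
                 bmh_net_config(backbone_hidden = 4, epochs = 2))
  expect_error(predict(fit, list(betti = tf$betti[, 1:5], conn = tf$conn)),
               "Betti")
  expect_error(predict(fit, list(betti = tf$betti, conn = tf$conn[, 1:3])),
               "connectome")
})

test_that("training reduces the loss and is seed-reproducible", {
  tf <- make_toy_features(signal = 1.5)
  cfg <- desk_config(backbone_hidden = 8, epochs = 50, seed = 11)
  fit <- bmh_net(tf$betti, tf$conn, tf$y, cfg)
  expect_lt(fit$losses[length(fit$losses)], fit$losses[1])
  fit2 <- bmh_net(tf$betti, tf$conn, tf$y, cfg)
  expect_identical(fit$params, fit2$params)
  expect_error(bmh_net(tf$betti, tf$conn, rep(1L, 12), cfg), "both classes")
})

test_that("a separable synthetic contrast yields higher scores for the positive class", {
  tf <- make_toy_features(n = 30, signal = 2, seed = 8)
  fit <- bmh_net(tf$betti, tf$conn, tf$y,
                 desk_config(backbone_hidden = 16, epochs = 150, seed = 2))
  sc <- predict(fit, list(betti = tf$betti, conn = tf$conn))
  expect_gt(mean(sc[tf$y == 1]), mean(sc[tf$y == 0]))
})

test_that("threshold selection maximizes F-score with documented edge cases", {
  # perfectly separated
  ev <- evaluate(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(ev$f_score, 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$sensitivity, 1)
  # all scores equal: forced all-positive prediction
  ev2 <- evaluate(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(ev2$f_score, 2 * 0.5 / 1.5)
  expect_equal(ev2$sensitivity, 1)
  # hand-evaluated 8-subject toy: best F = 0.8 between 0.2 and 0.35
  scores <- c(0.1, 0.2, 0.35, 0.4, 0.6, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 1, 0, 1, 1, 0, 1)
  ev3 <- evaluate(scores, labels)
  expect_equal(ev3$f_score, 0.8)
  expect_equal(ev3$accuracy, 0.75)
  expect_equal(ev3$precision, 2 / 3)
  expect_equal(ev3$sensitivity, 1)
  expect_equal(ev3$binarization_threshold, 0.275)
  # no positive labels: flagged, not silently zero
  ev4 <- evaluate(c(0.2, 0.8), c(0, 0))
  expect_true(ev4$undefined_sensitivity)
  expect_true(is.na(ev4$f_score))
})

test_that("evaluation is invariant under strictly monotone score transforms", {
  set.seed(4)
  scores <- runif(20)
  labels <- rbinom(20, 1, 0.5)
  labels[1] <- 1
  ev <- evaluate(scores, labels)
  ev_sq <- evaluate(scores^2, labels)
  for (m in c("f_score", "accuracy", "precision", "sensitivity")) {
    expect_equal(ev[[m]], ev_sq[[m]])
  }
})

test_that("gradient importance localizes to the subnetworks the network reads", {
  tf <- make_toy_features(n = 10, db = 24, dc = 6)
  fmap <- rep(rep(c("A", "B", "C"), each = 4), 2)  # 3 subnetworks, T = 4
  cfg <- bmh_net_config(backbone_hidden = 6, epochs = 3, standardize = FALSE,
                        seed = 9)
  fit <- bmh_net(tf$betti[, 1:24], tf$conn, tf$y, cfg)
  # zero Betti backbone: all importances vanish
  fit0 <- fit
  fit0$params$Wb[] <- 0
  imp0 <- subnetwork_importance(fit0, list(betti = tf$betti[, 1:24],
                                           conn = tf$conn),
                                feature_map = fmap)
  expect_true(all(imp0 == 0))
  # mask all inputs except subnetwork B's rows of the Betti backbone
  fitB <- fit
  fitB$params$Wb[fmap != "B", ] <- 0
  impB <- subnetwork_importance(fitB, list(betti = tf$betti[, 1:24],
                                           conn = tf$conn),
                                feature_map = fmap)
  expect_equal(unname(impB[c("A", "C")]), c(0, 0))
  expect_gt(impB[["B"]], 0)
  # mean over subjects: duplicating a subject leaves importance unchanged
  dup <- list(betti = tf$betti[c(1:10, 1:10), 1:24],
              conn = tf$conn[c(1:10, 1:10), ])
  imp_dup <- subnetwork_importance(fitB, dup, feature_map = fmap)
  expect_equal(imp_dup, impB)
})

test_that("label-permuted training stays near the chance-level F-score", {
  # no-signal features: validation F after argmax thresholding should sit
  # near the all-positive baseline (0.667 for balanced labels), far from 1
  fs <- vapply(1:8, function(r) {
    tf <- make_toy_features(n = 24, signal = 0, seed = 100 + r)
    tr <- 1:14; va <- 15:24
    fit <- bmh_net(tf$betti[tr, ], tf$conn[tr, ], tf$y[tr],
                   desk_config(backbone_hidden = 8, epochs = 60, seed = r))
    evaluate(predict(fit, list(betti = tf$betti[va, ],
                               conn = tf$conn[va, ])), tf$y[va])$f_score
  }, numeric(1))
  expect_lt(stats::median(fs), 0.93)
  expect_gt(stats::median(fs), 0.5)
})

test_that("group curve tests control the Holm family and flag injected shifts", {
  set.seed(55)
  n <- 16; d <- 30
  X <- matrix(rnorm(2 * n * d), 2 * n, d)
  g <- rep(0:1, each = n)
  # identical groups: nothing survives Holm
  res0 <- group_curve_test(X, g)
  expect_false(any(res0$significant_holm))
  # inject a large constant shift at one grid point
  X2 <- X
  X2[g == 1, 7] <- X2[g == 1, 7] + 50
  res1 <- group_curve_test(X2, g)
  expect_true(res1$significant_holm[7])
  expect_equal(which(res1$significant_holm), 7L)
  # Holm dominates raw p-values; adjusted flags are a subset of raw flags
  ok <- !is.na(res1$p_raw)
  expect_true(all(res1$p_holm[ok] >= res1$p_raw[ok]))
  expect_true(all(which(res1$significant_holm) %in%
                    which(res1$significant_raw)))
  # zero variance in both groups is flagged, not given a fake p-value
  X3 <- X
  X3[, 3] <- 1
  res2 <- group_curve_test(X3, g)
  expect_true(res2$zero_variance[3])
  expect_true(is.na(res2$p_raw[3]))
})

test_that("cross-validation harness aggregates metrics and importance", {
  tf <- make_toy_features(n = 20, db = 16, dc = 6, signal = 1.2, seed = 21)
  fmap <- rep(rep(c("A", "B"), each = 4), 2)
  cv <- bmh_cv(tf$betti, tf$conn, tf$y,
               config = desk_config(backbone_hidden = 6, epochs = 40),
               folds = 4, seeds = 1:2, feature_map = fmap)
  expect_equal(nrow(cv$metrics), 8)
  expect_true(all(cv$metrics$f_score >= 0 & cv$metrics$f_score <= 1,
                  na.rm = TRUE))
  expect_equal(sort(cv$importance_summary$subnetwork), c("A", "B"))
  expect_true(all(cv$importance_summary$mean >= 0))
})
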