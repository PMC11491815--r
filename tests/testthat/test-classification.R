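test_that("windowing drops trailing partial windows", {
  w <- make_windows(100, 16)
  expect_equal(nrow(w), 6)                      # floor(100/16), 4 samples dropped
  expect_equal(w$start[1], 1)
  expect_equal(w$end[6], 96)
  expect_equal(nrow(make_windows(16, 16)), 1)
  expect_equal(nrow(make_windows(15, 16)), 0)   # shorter than one window: empty, no error
  expect_error(make_windows(100, 1), ">= 2")
})

test_that("feature extraction matches simple oracles", {
  # constant window: sds, correlations, skewness/kurtosis, VeDBA all 0
  f <- extract_features(constant_trace(16), window_samples = 16)
  expect_equal(nrow(f), 1)
  expect_equal(f$ax_sd, 0)
  expect_equal(f$corr_xy, 0)
  expect_equal(f$az_skew, 0)
  expect_equal(f$vedba_mean, 0)
  expect_equal(f$vedba_max, 0)

  # pure 20 Hz sinusoid at 100 Hz, 100-sample window: dominant bin = 20 Hz
  t <- (0:99) / 100
  tr <- accel_trace(rep(0, 100), rep(0, 100), sin(2 * pi * 20 * t), 100)
  f2 <- extract_features(tr, window_samples = 100)
  expect_equal(f2$zfreq_hz, 20)

  # alternating z = 1,1,3,3,... over 16 samples: mean 2
  z <- rep(c(1, 1, 3, 3), 4)
  tr3 <- accel_trace(rep(0, 16), rep(0, 16), z, 25)
  expect_equal(extract_features(tr3, window_samples = 16)$az_mean, 2)
})

test_that("feature rows are window-independent (order relabelling invariance)", {
  out <- generate_trace(quick_config(duration = 60))
  f <- extract_features(out$trace, window_samples = 16)
  w <- make_windows(out$trace, 16)
  # recompute feature row 5 from a trace cut to exactly that window
  idx <- w$start[5]:w$end[5]
  sub <- accel_trace(out$trace$samples[idx, "ax"], out$trace$samples[idx, "ay"],
                     out$trace$samples[idx, "az"], out$trace$sample_rate)
  f5 <- extract_features(sub, window_samples = 16)
  expect_equal(unlist(f[5, ]), unlist(f5[1, ]))
})

test_that("the classifier learns a separable problem and reproduces its labels", {
  set.seed(11)
  n <- 40
  feats <- data.frame(a = c(rnorm(n, 0), rnorm(n, 10)), b = rnorm(2 * n),
                      class = rep(c("flying", "inactive"), each = n))
  model <- train_classifier(feats, seed = 1)
  expect_identical(predict_behaviors(model, feats), feats$class)
  expect_error(train_classifier(feats[feats$class == "flying", ]), "2 classes")
  expect_error(train_classifier(feats[c(1:40, 41:45), ]), ">= 10 rows")
  expect_error(predict_behaviors(model, feats[, "a", drop = FALSE]),
               "missing feature column")
})

test_that("a reloaded model gives identical predictions", {
  set.seed(12)
  n <- 30
  feats <- data.frame(a = c(rnorm(n, 0), rnorm(n, 3), rnorm(n, -3)),
                      b = rnorm(3 * n),
                      class = rep(c("flying", "inactive", "preening"), each = n))
  model <- train_classifier(feats, seed = 2)
  path <- file.path(tempdir(), "clf.ubj")
  save_classifier(model, path)
  model2 <- load_classifier(path)
  expect_identical(predict_behaviors(model2, feats), predict_behaviors(model, feats))
  expect_identical(model2$classes, model$classes)
  # retraining with the same seed is reproducible
  model3 <- train_classifier(feats, seed = 2)
  expect_identical(predict_behaviors(model3, feats), predict_behaviors(model, feats))
  expect_equal(length(predict_behaviors(model, feats)), nrow(feats))
})

test_that("training on permuted labels yields chance-level held-out accuracy", {
  out <- generate_trace(synthetic_config(sample_rate = 23, session_duration = 1200,
                                         seed = 31))
  feats <- extract_features(out$trace, labels = out$truth$labels)
  classes <- unique(feats$class)
  set.seed(13)
  feats$class <- sample(feats$class)            # destroy the signal
  idx <- sample(nrow(feats))
  ntr <- floor(0.8 * nrow(feats))
  model <- train_classifier(feats[idx[1:ntr], ], seed = 3)
  pred <- predict_behaviors(model, feats[idx[-(1:ntr)], ])
  acc <- mean(pred == feats$class[idx[-(1:ntr)]])
  # permuted labels are not uniform over classes; chance level is the
  # frequency-weighted match rate, bounded crudely by 1/K +/- 0.1 plus the
  # imbalance head start of always-guessing the majority class
  expect_lt(acc, max(table(feats$class)) / nrow(feats) + 0.1)
})

test_that("confusion matrices count, and report recall/precision in percent", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "a", "b"))
  expect_true(all(cm$counts[upper.tri(cm$counts) | lower.tri(cm$counts)] == 0))
  expect_equal(unname(cm$recall_pct), c(100, 100))

  # 5 correct of 13 true windows: recall 38.46%
  true <- rep("bill_wiping", 13)
  pred <- c(rep("bill_wiping", 5), rep("food_shaking", 8))
  cm2 <- confusion_matrix(true, pred)
  expect_equal(unname(round(cm2$recall_pct["bill_wiping"], 2)), 38.46)

  # all predictions one class: that class recall 100, others 0
  cm3 <- confusion_matrix(c("a", "b", "b"), c("a", "a", "a"))
  expect_equal(unname(cm3$recall_pct), c(100, 0))
  expect_error(confusion_matrix(c("a"), c("a", "b")), "equal length")
})
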