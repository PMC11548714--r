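# CNN tests run on reduced sizes (short inputs, few epochs, small sets); the
# full-scale benchmark lives in test-acceptance.R.

test_that("trainable parameter count matches the layer-by-layer hand count", {
  cfg <- detector_config()
  # conv1: 1*3*32+32; BN1: 2*32; conv2: 32*3*32+32; BN2: 2*32; dense: 32*2+2
  expect_equal(build_detector(cfg)$n_params,
               (1 * 3 * 32 + 32) + 2 * 32 + (32 * 3 * 32 + 32) + 2 * 32 + (32 * 2 + 2))
  # parameter count is independent of the input length (GAP removes it)
  expect_equal(build_detector(detector_config(input_length = 120))$n_params,
               build_detector(detector_config(input_length = 200))$n_params)
  expect_pfmqa_error(detector_config(lr_reduce_factor = 1.2), "pfmqa_parameter_error")
  expect_pfmqa_error(detector_config(epochs = 0), "pfmqa_parameter_error")
})

test_that("softmax output is a probability vector for any input", {
  m <- build_detector(detector_config(input_length = 50, seed = 2))
  withr::with_seed(4, {
    X <- matrix(rnorm(5 * 50), 5, 50)
    P <- predict_detector(m, X)
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-6)
    expect_true(all(P >= 0))
  })
})

test_that("input preparation standardizes, pads and labels traces", {
  cfg <- detector_config(input_length = 200)
  short <- recording(rnorm(100, 3, 1), fs = 20, task = "rest")
  long <- recording(rnorm(250, 3, 1), fs = 20, task = "mvc")
  flat <- recording(rep(2, 120), fs = 20, task = "push")
  prep <- prepare_inputs(list(short, long, flat), cfg)
  expect_equal(dim(prep$X), c(3, 200))
  expect_equal(prep$y, c(1L, 2L, 1L))
  # standardized: zero mean, unit sd on the un-padded span
  expect_equal(mean(prep$X[1, 51:150]), 0, tolerance = 1e-9)
  expect_equal(sd(prep$X[1, 51:150]), 1, tolerance = 1e-9)
  # edge padding replicates edge values
  expect_equal(prep$X[1, 1:50], rep(prep$X[1, 51], 50))
  expect_equal(prep$X[1, 151:200], rep(prep$X[1, 150], 50))
  # constant trace becomes all zeros
  expect_equal(prep$X[3, ], rep(0, 200))
  hz <- recording(rnorm(100), fs = 1024, task = "rest")
  expect_error(prepare_inputs(list(hz), cfg), "downsample")
})

test_that("training is deterministic and separates a separable set", {
  cfg <- detector_config(epochs = 25, input_length = 120, seed = 13)
  items <- gen_recordings(list(mvc = 16, rest = 16),
                          generator_params(mvc_duration = 6, rest_duration = 6), seed = 21)
  prep <- prepare_inputs(items, cfg)
  tr <- list(X = prep$X[seq(1, 32, 2), ], y = prep$y[seq(1, 32, 2)])
  va <- list(X = prep$X[seq(2, 32, 2), ], y = prep$y[seq(2, 32, 2)])
  m1 <- train_detector(build_detector(cfg), tr, va)
  m2 <- train_detector(build_detector(cfg), tr, va)
  expect_identical(pfmqa:::flatten_params(m1$params), pfmqa:::flatten_params(m2$params))
  # separable by construction: high training accuracy
  acc <- mean(max.col(predict_detector(m1, tr$X)) == tr$y)
  expect_gte(acc, 0.99)
  expect_pfmqa_error(train_detector(build_detector(cfg), list(X = tr$X[0, , drop = FALSE],
                                                              y = integer(0)), va),
                     "pfmqa_parameter_error")
})

test_that("the plateau schedule reduces the rate and stops early on flat loss", {
  # constant inputs cannot improve the validation loss: LR halves after
  # lr_reduce_patience epochs and training stops at early_stop_patience
  cfg <- detector_config(epochs = 50, early_stop_patience = 8, lr_reduce_patience = 3,
                         input_length = 30, seed = 1)
  X <- matrix(0, 8, 30); y <- rep(c(1L, 2L), 4)
  m <- train_detector(build_detector(cfg), list(X = X, y = y), list(X = X, y = y))
  h <- m$history
  expect_lte(length(h$val_loss), 10)          # stopped well before 50
  expect_lt(min(h$lr), cfg$lr)                # at least one reduction fired
  expect_equal(h$lr[1], cfg$lr)
})

test_that("evaluation metrics and ROC behave at the extremes", {
  # perfect and inverted predictors via a degenerate 1-feature surrogate
  scores <- c(0.9, 0.8, 0.2, 0.1); labels <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc_curve(-scores, labels)$auc, 0)
  expect_pfmqa_error(roc_curve(scores, rep(TRUE, 4)), "pfmqa_parameter_error")
  # random scores on balanced labels: AUC near 1/2
  withr::with_seed(99, {
    sc <- runif(2000); lb <- rep(c(TRUE, FALSE), 1000)
    expect_equal(roc_curve(sc, lb)$auc, 0.5, tolerance = 0.05)
  })
})

test_that("own AUC agrees with pROC on seeded score sets", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    for (i in 1:5) {
      lb <- rep(c(0, 1), each = 40)
      sc <- rnorm(80, mean = lb)
      ours <- roc_curve(sc, lb == 1)$auc
      ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  })
})

test_that("evaluate_detector reports a consistent confusion matrix", {
  cfg <- detector_config(epochs = 15, input_length = 120, seed = 3)
  items <- gen_recordings(list(mvc = 12, rest = 12),
                          generator_params(mvc_duration = 6, rest_duration = 6), seed = 33)
  prep <- prepare_inputs(items, cfg)
  m <- train_detector(build_detector(cfg), prep, prep)
  res <- evaluate_detector(m, prep)
  expect_equal(sum(res$confusion), res$n)
  expect_equal(res$accuracy, sum(diag(res$confusion)) / res$n)
  expect_gte(res$auc, 0.99)
})

test_that("cross-validation partitions every recording into exactly one test fold", {
  cfg <- detector_config(seed = 7)
  items <- gen_recordings(list(mvc = 20, rest = 20), generator_params(), seed = 41)
  y <- prepare_inputs(items, cfg)$y
  fold <- pfmqa:::stratified_folds(y, 5L, 123L)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.vector(table(fold)), rep(8L, 5))
  expect_equal(as.vector(table(fold[y == 2L])), rep(4L, 5))  # stratified
  expect_identical(fold, pfmqa:::stratified_folds(y, 5L, 123L))
  expect_false(identical(fold, pfmqa:::stratified_folds(y, 5L, 124L)))
  expect_pfmqa_error(cross_validate_detector(items[1:6], cfg), "pfmqa_parameter_error")
})

test_that("checkpoints round-trip through the JSON format", {
  cfg <- detector_config(epochs = 3, input_length = 60, seed = 17)
  items <- gen_recordings(list(mvc = 8, rest = 8),
                          generator_params(mvc_duration = 5, rest_duration = 3), seed = 55)
  prep <- prepare_inputs(items, cfg)
  m <- train_detector(build_detector(cfg), prep, prep)
  f <- withr::local_tempfile(fileext = ".json")
  save_detector(m, f)
  m2 <- load_detector(f)
  expect_equal(predict_detector(m2, prep$X), predict_detector(m, prep$X), tolerance = 1e-12)
})
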