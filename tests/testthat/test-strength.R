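# brute-force confusion-matrix oracle, independent of evaluate_strength
brute_report <- function(true, pred, classes) {
  conf <- matrix(0L, length(classes), length(classes), dimnames = list(classes, classes))
  for (i in seq_along(true))
    conf[as.character(true[i]), as.character(pred[i])] <-
      conf[as.character(true[i]), as.character(pred[i])] + 1L
  list(accuracy = sum(diag(conf)) / length(true), conf = conf)
}

make_feature_df <- function(n, seed) {
  items <- gen_recordings(list(mvc = n), generator_params(), seed = seed)
  df <- features_to_df(lapply(items, function(it) extract_features(it$recording)))
  df$mos <- vapply(items, function(it) it$recording$mos, integer(1))
  normalize_features(df)$table
}

test_that("stratified split preserves class proportions and is seeded", {
  df <- data.frame(x = 1:100, mos = rep(1:5, each = 20))
  df[paste0(pfmqa:::.feature_cols, "_norm")] <- runif(100)
  sp <- split_dataset(df, 0.2, seed = 9)
  expect_equal(nrow(sp$test), 20)
  expect_equal(as.vector(table(sp$test$mos)), rep(4L, 5))
  sp2 <- split_dataset(df, 0.2, seed = 9)
  expect_identical(sp$test$x, sp2$test$x)
  expect_false(identical(sp$test$x, split_dataset(df, 0.2, seed = 10)$test$x))
  singleton <- df[c(1:60, 100), ]
  expect_pfmqa_error(split_dataset(singleton, 0.2, seed = 1), "pfmqa_parameter_error")
})

test_that("evaluate_strength matches hand-computed examples", {
  # both predictions one class away: all hits under the +/-1 margin
  expect_equal(evaluate_strength(c(3, 3), c(2, 4), tolerance = 1)$accuracy, 1)
  # exact scoring: accuracy 2/3, class-2 recall 1/2, class-2 precision 1/1
  rep0 <- evaluate_strength(c(1, 2, 2), c(1, 2, 3), tolerance = 0)
  expect_equal(rep0$accuracy, 2 / 3)
  pc <- rep0$per_class
  expect_equal(pc$recall[pc$class == 2], 1 / 2)
  expect_equal(pc$precision[pc$class == 2], 1)
  expect_pfmqa_error(evaluate_strength(1:3, 1:2), "pfmqa_parameter_error")
})

test_that("tolerance-0 scoring matches the brute-force oracle on 1000 random pairs", {
  withr::with_seed(77, {
    true <- sample(1:5, 1000, replace = TRUE)
    pred <- sample(1:5, 1000, replace = TRUE)
  })
  rep0 <- evaluate_strength(true, pred, tolerance = 0, classes = 1:5)
  oracle <- brute_report(true, pred, 1:5)
  expect_equal(rep0$accuracy, oracle$accuracy)
  expect_equal(unclass(unname(as.matrix(rep0$confusion))), unclass(unname(oracle$conf)))
  for (cl in 1:5) {
    tp <- oracle$conf[cl, cl]
    fp <- sum(oracle$conf[-cl, cl]); fn <- sum(oracle$conf[cl, -cl])
    pc <- rep0$per_class[rep0$per_class$class == cl, ]
    expect_equal(pc$tp, tp); expect_equal(pc$fp, fp); expect_equal(pc$fn, fn)
    expect_equal(pc$precision, tp / (tp + fp))
    expect_equal(pc$recall, tp / (tp + fn))
  }
  # weighted recall equals accuracy at tolerance 0 (algebraic identity)
  expect_equal(unname(rep0$weighted["recall"]), rep0$accuracy)
  # macro F1 is the harmonic mean of macro P and macro R, not a mean of F1s
  pm <- mean(rep0$per_class$precision); rm_ <- mean(rep0$per_class$recall)
  expect_equal(unname(rep0$macro["f1"]), 2 * pm * rm_ / (pm + rm_))
})

test_that("the +/-1 margin only ever adds hits", {
  withr::with_seed(78, {
    for (i in 1:25) {
      true <- sample(1:5, 40, replace = TRUE)
      pred <- sample(1:5, 40, replace = TRUE)
      a0 <- evaluate_strength(true, pred, 0)$accuracy
      a1 <- evaluate_strength(true, pred, 1)$accuracy
      expect_gte(a1, a0)
    }
  })
})

test_that("training on one class predicts that class; rfc is deterministic", {
  df <- make_feature_df(20, seed = 61)
  one <- df[df$mos == 3, ]
  m <- suppressMessages(train_strength(one, "rfc", seed = 5))
  expect_equal(predict_mos(m, df), rep(3L, nrow(df)))
  m1 <- train_strength(df, "rfc", seed = 6)
  m2 <- train_strength(df, "rfc", seed = 6)
  expect_identical(predict_mos(m1, df), predict_mos(m2, df))
  expect_equal(predict_mos(m1, df[0, ]), integer(0))
  expect_pfmqa_error(predict_mos(m1, data.frame(x = 1)), "pfmqa_parameter_error")
  expect_error(train_strength(df, "nope"))
})

test_that("every method learns the synthetic grade structure within the margin", {
  df <- make_feature_df(150, seed = 62)
  sp <- split_dataset(df, 0.2, seed = 7)
  for (meth in c("rfc", "trfc", "xgb", "lr")) {
    m <- train_strength(sp$train, meth, seed = 7)
    acc_tr <- evaluate_strength(sp$train$mos, predict_mos(m, sp$train), 1)$accuracy
    expect_gte(acc_tr, 0.95)
    if (meth == "trfc") expect_length(m$selected_features, 4)
  }
})

test_that("grade-0 rows are excluded by default and kept on request", {
  df <- make_feature_df(30, seed = 63)
  df$mos[1:3] <- 0L
  expect_message(m <- train_strength(df, "rfc", seed = 2), "grade-0")
  expect_false(0L %in% m$levels)
  m0 <- suppressMessages(train_strength(df, "rfc", seed = 2, include_grade0 = TRUE))
  expect_true(0L %in% m0$levels)
})

test_that("buttock-movement rows can be excluded by flag", {
  df <- make_feature_df(30, seed = 64)
  df$buttock_movement <- rep(c(TRUE, FALSE), 15)
  m <- train_strength(df, "rfc", seed = 3, exclude_buttock = TRUE)
  expect_s3_class(m, "pfm_strength_model")
})
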