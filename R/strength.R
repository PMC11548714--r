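# Prediction of the Modified Oxford Scale (MOS) grade from normalized
# contraction features, evaluated with a +/-1-class tolerance that reflects
# the inter-rater variability of digital palpation. Grade 0 (nil) is excluded
# by default: virtually absent in practice from cohorts able to contract.

#' Stratified train/test split
#'
#' Random split preserving the class proportions (the class imbalance of the
#' data is maintained), deterministic under the seed.
#'
#' @param df data frame with a label column.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed.
#' @param label name of the label column (default `"mos"`).
#' @return A list with `train` and `test` data frames.
#' @export
split_dataset <- function(df, test_fraction = 0.2, seed = 1L, label = "mos") {
  if (!label %in% names(df)) stop_parameter(sprintf("missing label column '%s'", label))
  y <- df[[label]]
  counts <- table(y)
  if (any(counts < 2L))
    stop_parameter(sprintf("class %s has fewer than 2 rows; cannot split with stratification",
                           names(counts)[which(counts < 2L)[1L]]))
  test_idx <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cl in names(counts)) {
      idx <- which(y == cl)
      k <- round(length(idx) * test_fraction)
      k <- min(max(k, 1L), length(idx) - 1L)
      test_idx <- c(test_idx, sample(idx, k))
    }
  })
  list(train = df[-test_idx, , drop = FALSE], test = df[sort(test_idx), , drop = FALSE])
}

.strength_methods <- c("rfc", "trfc", "xgb", "lr")

strength_feature_cols <- function(df) {
  cols <- paste0(.feature_cols, "_norm")
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop_parameter(paste("missing feature column:", missing[1L]))
  cols
}

#' Train an MOS strength classifier
#'
#' Methods: `rfc` (random forest, 100 trees), `trfc` ("top" random forest:
#' fit an RFC, rank features by importance, refit on the top-`k` subset),
#' `xgb` (gradient-boosted trees) and `lr` (multinomial logistic regression
#' with a small L2 penalty). Inputs are the normalized features in \[0, 1\]
#' (`*_norm` columns); labels are MOS grades 1--5 in column `mos`.
#'
#' @param train data frame of normalized features plus `mos`.
#' @param method one of `"rfc"`, `"trfc"`, `"xgb"`, `"lr"`.
#' @param seed integer seed.
#' @param top_k number of features kept by `trfc` (default 4).
#' @param ntree random-forest size (default 100).
#' @param exclude_buttock drop rows whose `buttock_movement` annotation is
#'   `TRUE` before training.
#' @param include_grade0 keep MOS grade-0 rows (dropped by default).
#' @return A list of class `pfm_strength_model`.
#' @export
train_strength <- function(train, method = c("rfc", "trfc", "xgb", "lr"),
                           seed = 1L, top_k = 4L, ntree = 100L,
                           exclude_buttock = FALSE, include_grade0 = FALSE) {
  method <- match.arg(method)
  if (exclude_buttock && "buttock_movement" %in% names(train))
    train <- train[!vapply(train$buttock_movement, isTRUE, logical(1)), , drop = FALSE]
  if (!include_grade0 && any(train$mos == 0L, na.rm = TRUE)) {
    message(sprintf("dropping %d grade-0 row(s); set include_grade0 = TRUE to keep them",
                    sum(train$mos == 0L, na.rm = TRUE)))
    train <- train[train$mos != 0L, , drop = FALSE]
  }
  cols <- strength_feature_cols(train)
  if (nrow(train) < 2L) stop_parameter("need at least 2 training rows")
  y <- as.integer(train$mos)
  lo <- if (include_grade0) 0L else 1L
  if (any(is.na(y)) || any(y < lo | y > 5L)) stop_parameter("labels must be MOS grades in range")
  xmat <- as.matrix(train[cols])
  levels_present <- sort(unique(y))
  yf <- factor(y, levels = levels_present)
  if (length(levels_present) < 2L) {
    # degenerate single-class data: every method predicts that class
    return(structure(list(method = method, fitted = levels_present,
                          feature_cols = cols, levels = levels_present,
                          selected_features = if (method == "trfc") cols[seq_len(min(top_k, length(cols)))],
                          seed = as.integer(seed)),
                     class = "pfm_strength_model"))
  }

  fitted <- withr::with_seed(as.integer(seed), switch(
    method,
    rfc = randomForest::randomForest(x = xmat, y = yf, ntree = ntree),
    trfc = {
      rf0 <- randomForest::randomForest(x = xmat, y = yf, ntree = ntree, importance = FALSE)
      imp <- randomForest::importance(rf0)[, 1L]
      keep <- names(sort(imp, decreasing = TRUE))[seq_len(min(top_k, length(imp)))]
      list(rf = randomForest::randomForest(x = xmat[, keep, drop = FALSE], y = yf, ntree = ntree),
           keep = keep)
    },
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(xmat, label = match(y, levels_present) - 1L)
      xgboost::xgb.train(params = list(objective = "multi:softmax",
                                       num_class = length(levels_present),
                                       max_depth = 4L, eta = 0.3, nthread = 1L,
                                       seed = as.integer(seed)),
                         data = dtrain, nrounds = 50L, verbose = 0L)
    },
    lr = {
      dat <- data.frame(train[cols], .y = yf)
      utils::capture.output(
        m <- nnet::multinom(.y ~ ., data = dat, decay = 1e-3, maxit = 500L, trace = FALSE))
      m
    }
  ))
  structure(list(method = method, fitted = fitted, feature_cols = cols,
                 levels = levels_present,
                 selected_features = if (method == "trfc") fitted$keep else NULL,
                 seed = as.integer(seed)),
            class = "pfm_strength_model")
}

#' @export
print.pfm_strength_model <- function(x, ...) {
  cat(sprintf("<strength model> method=%s  classes={%s}\n", x$method,
              paste(x$levels, collapse = ",")))
  if (!is.null(x$selected_features))
    cat("  selected features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Predict MOS grades
#'
#' Feature values are clipped to \[0, 1\] before prediction (they are
#' normalized quantities by contract).
#'
#' @param model a [train_strength()] model.
#' @param rows data frame carrying the features the model was trained on.
#' @return Integer vector of grades in 1--5 (empty input gives empty output).
#' @export
predict_mos <- function(model, rows) {
  stopifnot(inherits(model, "pfm_strength_model"))
  if (nrow(rows) == 0L) return(integer(0))
  missing <- setdiff(model$feature_cols, names(rows))
  if (length(missing)) stop_parameter(paste("missing feature:", missing[1L]))
  xm <- as.matrix(rows[model$feature_cols])
  xm[] <- pmin(1, pmax(0, xm))
  if (length(model$levels) < 2L) return(rep(model$levels, nrow(rows)))
  pred <- switch(model$method,
    rfc = as.integer(as.character(predict(model$fitted, xm))),
    trfc = as.integer(as.character(predict(model$fitted$rf, xm[, model$fitted$keep, drop = FALSE]))),
    xgb = model$levels[predict(model$fitted, xgboost::xgb.DMatrix(xm)) + 1L],
    lr = {
      nd <- as.data.frame(xm)
      as.integer(as.character(predict(model$fitted, newdata = nd)))
    })
  as.integer(pred)
}

#' Evaluate MOS predictions with a class-tolerance margin
#'
#' With `tolerance = 1`, a prediction within one grade of the truth counts as
#' a hit for the true class: it is scored as if it were the true class, so it
#' contributes a TP to the true class and no FP to the neighbouring class.
#' With `tolerance = 0` this reduces to the ordinary confusion matrix.
#' Per-class precision/recall/F1 are reported together with macro averages
#' (unweighted means of per-class precision and recall, macro F1 their
#' harmonic mean) and the count-weighted (micro) averages
#' \eqn{P_w = \sum TP_c / \sum(TP_c + FP_c)},
#' \eqn{R_w = \sum TP_c / \sum(TP_c + FN_c)}; at tolerance 0 the weighted
#' recall equals the overall accuracy.
#'
#' @param true,pred integer grade vectors of equal length.
#' @param tolerance 0 or 1 (default 1).
#' @param classes class labels to report (default: the sorted classes observed
#'   in `true` and `pred`).
#' @return A list of class `pfm_strength_report`: `accuracy`, `per_class`
#'   (data frame with tp/fp/fn/tn, accuracy, precision, recall, f1, support),
#'   `macro` and `weighted` (precision, recall, f1), `confusion`.
#' @export
evaluate_strength <- function(true, pred, tolerance = 1L, classes = NULL) {
  if (length(true) != length(pred)) stop_parameter("true and pred must have equal length")
  if (length(true) == 0L) stop_parameter("empty input")
  if (!tolerance %in% c(0L, 1L)) stop_parameter("tolerance must be 0 or 1")
  if (is.null(classes)) classes <- sort(unique(c(true, pred)))
  # score within-tolerance predictions as the true class
  eff <- ifelse(abs(pred - true) <= tolerance, true, pred)
  n <- length(true)
  conf <- table(factor(true, levels = classes), factor(eff, levels = classes))
  per <- lapply(classes, function(cl) {
    tp <- sum(true == cl & eff == cl)
    fp <- sum(true != cl & eff == cl)
    fn <- sum(true == cl & eff != cl)
    tn <- n - tp - fp - fn
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               accuracy = (tp + tn) / n, precision = p, recall = r, f1 = f1,
               support = sum(true == cl))
  })
  per <- do.call(rbind, per)
  pm <- mean(per$precision, na.rm = TRUE)
  rm_ <- mean(per$recall, na.rm = TRUE)
  f1m <- if (pm + rm_ > 0) 2 * pm * rm_ / (pm + rm_) else NA_real_
  pw <- sum(per$tp) / sum(per$tp + per$fp)
  rw <- sum(per$tp) / sum(per$tp + per$fn)
  f1w <- if (pw + rw > 0) 2 * pw * rw / (pw + rw) else NA_real_
  structure(list(
    accuracy = sum(abs(pred - true) <= tolerance) / n,
    tolerance = as.integer(tolerance),
    per_class = per,
    macro = c(precision = pm, recall = rm_, f1 = f1m),
    weighted = c(precision = pw, recall = rw, f1 = f1w),
    confusion = conf,
    n = n
  ), class = "pfm_strength_report")
}

#' @export
print.pfm_strength_report <- function(x, ...) {
  cat(sprintf("<strength eval> n=%d  tolerance=%d  accuracy=%.4f\n", x$n, x$tolerance, x$accuracy))
  cat(sprintf("  macro    P=%.3f R=%.3f F1=%.3f\n", x$macro[1], x$macro[2], x$macro[3]))
  cat(sprintf("  weighted P=%.3f R=%.3f F1=%.3f\n", x$weighted[1], x$weighted[2], x$weighted[3]))
  invisible(x)
}
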