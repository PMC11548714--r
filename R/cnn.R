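# 1D stacked convolutional network for PFM contraction detection.
#
# Architecture: input -> conv(32 filters, kernel 3) -> batch norm -> ReLU ->
# conv(32, 3) -> batch norm -> ReLU -> global average pooling over time ->
# dense softmax. Trained with Adam on the sparse categorical cross-entropy,
# batch size 32, up to 100 epochs, early stopping (patience 50) and
# learning-rate reduction on plateau (factor 0.5, patience 20).
#
# The network is small enough that the forward/backward passes are plain
# matrix algebra: convolutions are evaluated as sums of shifted GEMMs on a
# (batch x time)-flattened activation matrix (samples vary fastest).

.bn_eps <- 1e-3
.bn_momentum <- 0.9

#' Configuration of the contraction detector
#'
#' Defaults follow the training recipe: two conv layers with 32 filters of
#' width 3, 100 epochs, batch size 32, early-stop patience 50 epochs,
#' learning-rate reduction by 0.5 after 20 epochs without validation-loss
#' improvement, Adam with initial learning rate `1e-3`. Input traces are
#' standardized per trace and padded/truncated to `input_length` samples
#' (10 s at 20 Hz).
#'
#' @param n_classes number of output classes (2: contraction vs non-contraction).
#' @param filters,kernel convolution filters and kernel width.
#' @param epochs,batch_size training schedule.
#' @param early_stop_patience,lr_reduce_patience,lr_reduce_factor plateau
#'   schedule on the validation loss.
#' @param input_length fixed input length in samples.
#' @param lr initial Adam learning rate.
#' @param val_fraction fraction of the training split held out (stratified)
#'   for validation inside [cross_validate_detector()].
#' @param seed integer seed driving weight init, shuffling and splits.
#' @return A list of class `pfm_detector_config`.
#' @export
detector_config <- function(n_classes = 2L, filters = 32L, kernel = 3L,
                            epochs = 100L, batch_size = 32L,
                            early_stop_patience = 50L, lr_reduce_patience = 20L,
                            lr_reduce_factor = 0.5, input_length = 200L,
                            lr = 1e-3, val_fraction = 0.2, seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes), filters = as.integer(filters),
              kernel = as.integer(kernel), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              early_stop_patience = as.integer(early_stop_patience),
              lr_reduce_patience = as.integer(lr_reduce_patience),
              lr_reduce_factor = lr_reduce_factor,
              input_length = as.integer(input_length), lr = lr,
              val_fraction = val_fraction, seed = as.integer(seed))
  counts <- c(cfg$n_classes, cfg$filters, cfg$kernel, cfg$epochs, cfg$batch_size,
              cfg$early_stop_patience, cfg$lr_reduce_patience, cfg$input_length)
  if (any(counts < 1L)) stop_parameter("all detector counts must be positive")
  if (cfg$lr_reduce_factor <= 0 || cfg$lr_reduce_factor >= 1)
    stop_parameter("lr_reduce_factor must be in (0, 1)")
  if (cfg$input_length < 2L * cfg$kernel) stop_parameter("input_length too small for the kernel")
  structure(cfg, class = "pfm_detector_config")
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained contraction detector
#'
#' Initialises the weights (Glorot uniform, seeded from the config) for the
#' conv/batch-norm/GAP/softmax stack. The trainable parameter count is
#' deterministic in the configuration and independent of the input length
#' (global average pooling removes the length dependence).
#'
#' @param cfg a [detector_config()].
#' @return A list of class `pfm_detector` with elements `cfg`, `params`,
#'   `bn_stats`, `n_params`, `trained`.
#' @export
build_detector <- function(cfg = detector_config()) {
  if (!inherits(cfg, "pfm_detector_config")) stop_parameter("cfg must be a detector_config()")
  f <- cfg$filters; k <- cfg$kernel; ncl <- cfg$n_classes
  params <- withr::with_seed(cfg$seed, {
    list(
      W1 = glorot(k, f, fan_in = k * 1L, fan_out = k * f),
      b1 = numeric(f),
      g1 = rep(1, f), be1 = numeric(f),
      W2 = lapply(seq_len(k), function(i) glorot(f, f, fan_in = k * f, fan_out = k * f)),
      b2 = numeric(f),
      g2 = rep(1, f), be2 = numeric(f),
      Wd = glorot(f, ncl, fan_in = f, fan_out = ncl),
      bd = numeric(ncl)
    )
  })
  n_params <- (k * 1L * f + f) + 2L * f + (k * f * f + f) + 2L * f + (f * ncl + ncl)
  structure(list(cfg = cfg, params = params,
                 bn_stats = list(rm1 = numeric(f), rv1 = rep(1, f),
                                 rm2 = numeric(f), rv2 = rep(1, f)),
                 n_params = n_params, trained = FALSE),
            class = "pfm_detector")
}

#' @export
print.pfm_detector <- function(x, ...) {
  cat(sprintf("<pfm_detector> conv(%d,%d)-BN-ReLU x2 -> GAP -> dense(%d)  %d trainable params%s\n",
              x$cfg$filters, x$cfg$kernel, x$cfg$n_classes, x$n_params,
              if (x$trained) "  [trained]" else ""))
  invisible(x)
}

# row indices selecting time offset k-1 from an (n*T_in)-row activation matrix
shift_idx <- function(n, t_out, k) {
  as.vector(outer(seq_len(n), (seq_len(t_out) + k - 2L) * n, "+"))
}

# small per-column broadcast matrix (cold paths only)
bcol <- function(n, v) matrix(v, n, length(v), byrow = TRUE)

# Batch norm over an affine conv output Z + b. In training mode the batch
# mean absorbs the conv bias exactly, so the normalization is computed on Z
# alone and the bias only enters the running statistics; the whole layer then
# collapses to one fused per-column affine evaluated by the C kernel.
bn_forward <- function(Z, b, gamma, beta, rm, rv, training) {
  n <- nrow(Z)
  if (training) {
    mu <- colMeans(Z)
    va <- cross_colsums(Z, Z) / n - mu^2
    inv <- 1 / sqrt(va + .bn_eps)
    s <- gamma * inv
    list(y = colscale_add(Z, s, beta - mu * s),
         Z = Z, mu = mu, va = va, inv = inv, s = s, run_mu = mu + b, run_va = va)
  } else {
    inv <- 1 / sqrt(rv + .bn_eps)
    s <- gamma * inv
    list(y = colscale_add(Z, s, beta + (b - rm) * s))
  }
}

# Gradient through batch statistics:
#   dZ = s * (dY - mean(dY) - xhat * mean(dY * xhat)),  xhat = (Z - mu) * inv
# expanded so it needs only column reductions and one fused kernel call.
bn_backward <- function(dY, bn, gamma) {
  n <- nrow(dY)
  mdY <- colMeans(dY)
  gx <- (cross_colsums(dY, bn$Z) / n - mdY * bn$mu) * bn$inv
  dZ <- colscale_two(dY, bn$Z, bn$s, -bn$s * bn$inv * gx,
                     bn$s * (bn$mu * bn$inv * gx - mdY))
  list(dZ = dZ, dgamma = gx * n, dbeta = mdY * n)
}

cnn_forward <- function(model, X, training = FALSE) {
  p <- model$params; cfg <- model$cfg; st <- model$bn_stats
  n <- nrow(X); L <- ncol(X); k <- cfg$kernel
  T1 <- L - k + 1L; T2 <- T1 - k + 1L
  V <- do.call(cbind, lapply(seq_len(k), function(j) as.vector(X[, j:(j + T1 - 1L), drop = FALSE])))
  Z1 <- V %*% p$W1
  bn1 <- bn_forward(Z1, p$b1, p$g1, p$be1, st$rm1, st$rv1, training)
  mask1 <- bn1$y > 0
  A1 <- bn1$y * mask1
  idx <- lapply(seq_len(k), function(j) shift_idx(n, T2, j))
  Z2 <- Reduce(`+`, lapply(seq_len(k), function(j) A1[idx[[j]], , drop = FALSE] %*% p$W2[[j]]))
  bn2 <- bn_forward(Z2, p$b2, p$g2, p$be2, st$rm2, st$rv2, training)
  mask2 <- bn2$y > 0
  A2 <- bn2$y * mask2
  G <- rowsum(A2, rep(seq_len(n), T2), reorder = TRUE) / T2
  logits <- G %*% p$Wd + bcol(n, p$bd)
  m <- logits[, 1L]
  for (j in seq_len(ncol(logits))[-1L]) m <- pmax(m, logits[, j])
  ez <- exp(logits - m)
  probs <- ez / rowSums(ez)
  list(probs = probs, V = V, bn1 = bn1, mask1 = mask1, A1 = A1,
       bn2 = bn2, mask2 = mask2, G = G, idx = idx, n = n, T1 = T1, T2 = T2)
}

cnn_backward <- function(model, fwd, y) {
  p <- model$params; k <- model$cfg$kernel
  n <- fwd$n; T2 <- fwd$T2
  dlogit <- fwd$probs
  dlogit[cbind(seq_len(n), y)] <- dlogit[cbind(seq_len(n), y)] - 1
  dlogit <- dlogit / n
  dWd <- crossprod(fwd$G, dlogit)
  dbd <- colSums(dlogit)
  dG <- dlogit %*% t(p$Wd)
  dA2 <- dG[rep(seq_len(n), T2), , drop = FALSE] / T2
  dA2 <- dA2 * fwd$mask2
  b2g <- bn_backward(dA2, fwd$bn2, p$g2)
  dZ2 <- b2g$dZ
  dW2 <- vector("list", k)
  dA1 <- matrix(0, nrow(fwd$A1), ncol(fwd$A1))
  for (j in seq_len(k)) {
    Aj <- fwd$A1[fwd$idx[[j]], , drop = FALSE]
    dW2[[j]] <- crossprod(Aj, dZ2)
    dA1[fwd$idx[[j]], ] <- dA1[fwd$idx[[j]], , drop = FALSE] + dZ2 %*% t(p$W2[[j]])
  }
  db2 <- colSums(dZ2)
  dA1 <- dA1 * fwd$mask1
  b1g <- bn_backward(dA1, fwd$bn1, p$g1)
  dW1 <- crossprod(fwd$V, b1g$dZ)
  db1 <- colSums(b1g$dZ)
  list(W1 = dW1, b1 = db1, g1 = b1g$dgamma, be1 = b1g$dbeta,
       W2 = dW2, b2 = db2, g2 = b2g$dgamma, be2 = b2g$dbeta,
       Wd = dWd, bd = dbd)
}

# flatten/unflatten the parameter list for the Adam state
flatten_grads <- function(g) {
  c(as.vector(g$W1), g$b1, g$g1, g$be1,
    unlist(lapply(g$W2, as.vector)), g$b2, g$g2, g$be2,
    as.vector(g$Wd), g$bd)
}

apply_flat <- function(params, flat, cfg) {
  k <- cfg$kernel; f <- cfg$filters; ncl <- cfg$n_classes
  pos <- 0L
  take <- function(n) { v <- flat[(pos + 1L):(pos + n)]; pos <<- pos + n; v }
  params$W1 <- matrix(take(k * f), k, f)
  params$b1 <- take(f); params$g1 <- take(f); params$be1 <- take(f)
  params$W2 <- lapply(seq_len(k), function(j) matrix(take(f * f), f, f))
  params$b2 <- take(f); params$g2 <- take(f); params$be2 <- take(f)
  params$Wd <- matrix(take(f * ncl), f, ncl)
  params$bd <- take(ncl)
  params
}

flatten_params <- function(p) flatten_grads(list(W1 = p$W1, b1 = p$b1, g1 = p$g1, be1 = p$be1,
                                                 W2 = p$W2, b2 = p$b2, g2 = p$g2, be2 = p$be2,
                                                 Wd = p$Wd, bd = p$bd))

cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

#' Prepare recordings as detector inputs
#'
#' Each trace is standardized to zero mean and unit variance (constant traces
#' become all zeros) and brought to the fixed input length by centred
#' edge-value padding or centred truncation. Labels: `mvc` is the contraction
#' class; `rest`, `cough` and `push` are non-contraction proxies.
#'
#' @param recs list of [recording()]s at 20 Hz (down-sample legacy recordings
#'   with [downsample()] first).
#' @param cfg a [detector_config()].
#' @return A list: `X` (matrix n x input_length), `y` (integer class ids,
#'   1 = non-contraction, 2 = contraction), `tasks`.
#' @export
prepare_inputs <- function(recs, cfg = detector_config()) {
  recs <- lapply(recs, function(r) if (inherits(r, "pfm_recording")) r else r$recording)
  L <- cfg$input_length
  X <- matrix(0, length(recs), L)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (abs(r$fs - 20) > 1e-6)
      stop_parameter(sprintf("recording %d is at %g Hz; downsample to 20 Hz first", i, r$fs))
    x <- r$samples
    s <- sd(x)
    x <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
    n <- length(x)
    if (n >= L) {
      start <- (n - L) %/% 2L
      X[i, ] <- x[(start + 1L):(start + L)]
    } else {
      left <- (L - n) %/% 2L
      X[i, ] <- c(rep(x[1L], left), x, rep(x[n], L - n - left))
    }
  }
  tasks <- vapply(recs, function(r) r$task, character(1))
  list(X = X, y = ifelse(tasks == "mvc", 2L, 1L), tasks = tasks)
}

#' Train the contraction detector
#'
#' Minibatch Adam on the sparse categorical cross-entropy, following the
#' configured schedule: validation loss evaluated after every epoch, learning
#' rate halved after `lr_reduce_patience` epochs without improvement, training
#' stopped after `early_stop_patience` epochs without improvement. All
#' randomness (shuffling) derives from the configuration seed, so two runs
#' from the same seed produce identical weights.
#'
#' @param model a [build_detector()] model.
#' @param train,val lists with elements `X` (matrix) and `y` (integer class
#'   ids), e.g. from [prepare_inputs()]; must be disjoint sets.
#' @return The trained model; `$history` holds per-epoch train/val losses,
#'   learning rates, and the stopping epoch.
#' @export
train_detector <- function(model, train, val) {
  stopifnot(inherits(model, "pfm_detector"))
  if (is.null(train$X) || nrow(train$X) == 0L) stop_parameter("empty training split")
  if (is.null(val$X) || nrow(val$X) == 0L) stop_parameter("empty validation split")
  cfg <- model$cfg
  ntr <- nrow(train$X)

  flat <- flatten_params(model$params)
  mS <- numeric(length(flat)); vS <- numeric(length(flat))
  tstep <- 0L
  lr <- cfg$lr
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-7

  best_val <- Inf; wait_es <- 0L; wait_lr <- 0L
  hist <- list(train_loss = numeric(0), val_loss = numeric(0), lr = numeric(0))

  withr::with_seed(child_seed(cfg$seed, 7L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(ntr)
      ep_loss <- 0; nb <- 0L
      for (bstart in seq(1L, ntr, by = cfg$batch_size)) {
        bidx <- ord[bstart:min(bstart + cfg$batch_size - 1L, ntr)]
        if (length(bidx) < 2L) next  # batch norm needs at least 2 rows
        fwd <- cnn_forward(model, train$X[bidx, , drop = FALSE], training = TRUE)
        # update running statistics
        model$bn_stats$rm1 <- .bn_momentum * model$bn_stats$rm1 + (1 - .bn_momentum) * fwd$bn1$run_mu
        model$bn_stats$rv1 <- .bn_momentum * model$bn_stats$rv1 + (1 - .bn_momentum) * fwd$bn1$run_va
        model$bn_stats$rm2 <- .bn_momentum * model$bn_stats$rm2 + (1 - .bn_momentum) * fwd$bn2$run_mu
        model$bn_stats$rv2 <- .bn_momentum * model$bn_stats$rv2 + (1 - .bn_momentum) * fwd$bn2$run_va
        ep_loss <- ep_loss + cross_entropy(fwd$probs, train$y[bidx]); nb <- nb + 1L
        g <- flatten_grads(cnn_backward(model, fwd, train$y[bidx]))
        tstep <- tstep + 1L
        mS <- beta1 * mS + (1 - beta1) * g
        vS <- beta2 * vS + (1 - beta2) * g^2
        flat <- flat - lr * (mS / (1 - beta1^tstep)) / (sqrt(vS / (1 - beta2^tstep)) + aeps)
        model$params <- apply_flat(model$params, flat, cfg)
      }
      vloss <- cross_entropy(cnn_forward(model, val$X, training = FALSE)$probs, val$y)
      hist$train_loss <- c(hist$train_loss, ep_loss / max(nb, 1L))
      hist$val_loss <- c(hist$val_loss, vloss)
      hist$lr <- c(hist$lr, lr)
      if (vloss < best_val - 1e-12) {
        best_val <- vloss; wait_es <- 0L; wait_lr <- 0L
      } else {
        wait_es <- wait_es + 1L; wait_lr <- wait_lr + 1L
        if (wait_lr >= cfg$lr_reduce_patience) { lr <- lr * cfg$lr_reduce_factor; wait_lr <- 0L }
        if (wait_es >= cfg$early_stop_patience) break
      }
    }
  })
  # re-estimate the batch-norm population statistics on the full training set
  # so inference does not depend on how many minibatch updates were run
  fin <- cnn_forward(model, train$X, training = TRUE)
  model$bn_stats <- list(rm1 = fin$bn1$run_mu, rv1 = fin$bn1$run_va,
                         rm2 = fin$bn2$run_mu, rv2 = fin$bn2$run_va)
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Class probabilities from a detector
#'
#' @param model a trained `pfm_detector`.
#' @param X input matrix (rows = traces), e.g. from [prepare_inputs()].
#' @return Matrix n x n_classes of softmax probabilities (rows sum to 1).
#' @export
predict_detector <- function(model, X) {
  cnn_forward(model, X, training = FALSE)$probs
}

#' ROC points and AUC from scores
#'
#' Sweeps all score thresholds and returns (FPR, TPR) points; the AUC is the
#' trapezoidal integral of TPR over FPR.
#'
#' @param scores numeric scores for the positive class.
#' @param labels logical or 0/1 vector (TRUE/1 = positive).
#' @return List with `points` (data frame fpr, tpr) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop_parameter("ROC needs both classes in the test set")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1))
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a detector on a test set
#'
#' Reports accuracy, sensitivity (recall of the contraction class),
#' specificity (recall of the non-contraction class), the 2x2 confusion
#' matrix, and the ROC/AUC computed from the contraction-class score. With a
#' single-class test set the defined metrics are still returned and the AUC
#' is `NA` with a warning.
#'
#' @param model a trained `pfm_detector`.
#' @param test list with `X` and `y` (1 = non-contraction, 2 = contraction).
#' @return A list of class `pfm_fold_result`.
#' @export
evaluate_detector <- function(model, test) {
  if (is.null(test$X) || nrow(test$X) == 0L) stop_parameter("empty test set")
  probs <- predict_detector(model, test$X)
  pred <- max.col(probs, ties.method = "first")
  y <- test$y
  tp <- sum(pred == 2L & y == 2L); tn <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 2L & y == 1L); fn <- sum(pred == 1L & y == 2L)
  roc <- tryCatch(roc_curve(probs[, 2L], y == 2L), error = function(e) {
    warning("AUC undefined: ", conditionMessage(e)); NULL
  })
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = matrix(c(tn, fn, fp, tp), 2L, 2L,
                       dimnames = list(predicted = c("non", "contraction"),
                                       true = c("non", "contraction"))),
    roc_points = if (is.null(roc)) NULL else roc$points,
    auc = if (is.null(roc)) NA_real_ else roc$auc,
    n = length(y)
  ), class = "pfm_fold_result")
}

#' @export
print.pfm_fold_result <- function(x, ...) {
  cat(sprintf("<detector eval> n=%d  acc=%.3f  sens=%.3f  spec=%.3f  AUC=%.3f\n",
              x$n, x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

# deal indices of each stratum round-robin into n_folds folds, shuffled
stratified_folds <- function(strata, n_folds, seed) {
  fold <- integer(length(strata))
  withr::with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Five-fold cross-validation of the contraction detector
#'
#' Stratified (by class, or by subject when `grouped`) five-fold partition;
#' in each round the held-out fold is tested and the remainder is split
#' 80/20 (stratified, seeded) into training and validation for the early
#' stopping schedule. Every recording is tested exactly once.
#'
#' @param recs list of [recording()]s (or items carrying `$recording`).
#' @param cfg a [detector_config()].
#' @param n_folds number of folds (default 5).
#' @param grouped if `TRUE`, folds are formed over subjects so no subject
#'   appears in both training and test.
#' @return A list of class `pfm_cv_result`: `folds` (per-fold results),
#'   `mean_accuracy`, `mean_sensitivity`, `mean_specificity`, `fold_of`.
#' @export
cross_validate_detector <- function(recs, cfg = detector_config(), n_folds = 5L,
                                    grouped = FALSE) {
  prep <- prepare_inputs(recs, cfg)
  y <- prep$y
  if (min(sum(y == 1L), sum(y == 2L)) < n_folds)
    stop_parameter(sprintf("need at least %d recordings per class", n_folds))
  if (grouped) {
    subj <- vapply(recs, function(r) (if (inherits(r, "pfm_recording")) r else r$recording)$subject_id,
                   character(1))
    us <- unique(subj)
    sf <- stratified_folds(rep(1L, length(us)), n_folds, child_seed(cfg$seed, 11L))
    fold <- sf[match(subj, us)]
  } else {
    fold <- stratified_folds(y, n_folds, child_seed(cfg$seed, 11L))
  }
  folds <- vector("list", n_folds)
  for (fd in seq_len(n_folds)) {
    test_i <- which(fold == fd)
    rest_i <- which(fold != fd)
    vmask <- stratified_folds(y[rest_i], round(1 / cfg$val_fraction),
                              child_seed(cfg$seed, 100L + fd)) == 1L
    tr_i <- rest_i[!vmask]; va_i <- rest_i[vmask]
    cfg_f <- cfg; cfg_f$seed <- child_seed(cfg$seed, 200L + fd)
    model <- build_detector(cfg_f)
    model <- train_detector(model,
                            list(X = prep$X[tr_i, , drop = FALSE], y = y[tr_i]),
                            list(X = prep$X[va_i, , drop = FALSE], y = y[va_i]))
    res <- evaluate_detector(model, list(X = prep$X[test_i, , drop = FALSE], y = y[test_i]))
    res$fold_index <- fd
    folds[[fd]] <- res
  }
  structure(list(
    folds = folds,
    mean_accuracy = mean(vapply(folds, `[[`, numeric(1), "accuracy")),
    mean_sensitivity = mean(vapply(folds, `[[`, numeric(1), "sensitivity")),
    mean_specificity = mean(vapply(folds, `[[`, numeric(1), "specificity")),
    fold_of = fold
  ), class = "pfm_cv_result")
}

#' @export
print.pfm_cv_result <- function(x, ...) {
  cat(sprintf("<%d-fold CV> mean acc=%.3f  sens=%.3f  spec=%.3f\n",
              length(x$folds), x$mean_accuracy, x$mean_sensitivity, x$mean_specificity))
  invisible(x)
}

#' Save / load a detector checkpoint (versioned JSON)
#'
#' @param model a `pfm_detector`.
#' @param path checkpoint path.
#' @return `save_detector`: the path, invisibly. `load_detector`: the model.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "pfm_detector"))
  obj <- list(format = "pfmqa-detector", version = 1L,
              cfg = unclass(model$cfg),
              flat = flatten_params(model$params),
              bn_stats = model$bn_stats,
              n_params = model$n_params, trained = model$trained)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pfmqa-detector")) stop_format("not a pfmqa detector checkpoint")
  cfg <- do.call(detector_config, obj$cfg[names(obj$cfg) != "class"])
  model <- build_detector(cfg)
  model$params <- apply_flat(model$params, obj$flat, cfg)
  model$bn_stats <- lapply(obj$bn_stats, as.numeric)
  model$trained <- isTRUE(obj$trained)
  model
}
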