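#' Root mean squared percentage error
#'
#' \deqn{RMSPE = \sqrt{\frac{1}{n}\sum_i \left(\frac{y_i - \hat y_i}{y_i}\right)^2} \times 100}
#'
#' Used both for signal-reconstruction fidelity and for feature-extraction
#' accuracy. Reference values too close to zero cannot anchor a relative
#' error: pairs with `|y| < 1e-9 * max(|y|)` are dropped, with a message when
#' any are; if all pairs are dropped an error is raised.
#'
#' @param y numeric vector of reference values.
#' @param yp numeric vector of predicted values, same length.
#' @return RMSPE in percent (scalar, >= 0).
#' @export
#' @examples
#' rmspe(c(100, 100), c(90, 110)) # 10
rmspe <- function(y, yp) {
  if (length(y) != length(yp)) stop_parameter("y and yp must have equal length")
  if (length(y) == 0L) stop_parameter("empty input")
  eps <- 1e-9 * max(abs(y))
  keep <- abs(y) >= eps & eps > 0
  if (!any(keep)) stop_parameter("all reference values are (near) zero; RMSPE undefined")
  if (any(!keep)) message(sprintf("rmspe: dropped %d pair(s) with near-zero reference", sum(!keep)))
  sqrt(mean(((y[keep] - yp[keep]) / y[keep])^2)) * 100
}

#' Error statistics between reference and predicted values
#'
#' Computes the forecasting errors `e_i = y_i - yp_i` and reports the mean
#' absolute error, the signed mean error, the sample standard deviation of the
#' errors (denominator n-1), and the RMSPE.
#'
#' @inheritParams rmspe
#' @return A list of class `pfm_error_report` with elements `mae`,
#'   `mean_error`, `sd_error`, `rmspe`, `n`.
#' @export
error_stats <- function(y, yp) {
  if (length(y) != length(yp)) stop_parameter("y and yp must have equal length")
  if (length(y) < 1L) stop_parameter("need at least one pair")
  e <- y - yp
  structure(list(
    mae = mean(abs(e)),
    mean_error = mean(e),
    sd_error = if (length(e) > 1L) sd(e) else 0,
    rmspe = suppressMessages(rmspe(y, yp)),
    n = length(e)
  ), class = "pfm_error_report")
}

#' @export
print.pfm_error_report <- function(x, ...) {
  cat(sprintf("<error report> n=%d  MAE=%.4g  mean error=%.4g  sd=%.4g  RMSPE=%.3f%%\n",
              x$n, x$mae, x$mean_error, x$sd_error, x$rmspe))
  invisible(x)
}

# Feature set reported in the extraction-accuracy table.
.validation_features <- c("rising_slope", "auc", "f_max", "f_avg", "relaxation")

#' Validate autonomous feature extraction against ground truth
#'
#' Runs a feature extractor over a set of recordings that carry generator
#' ground truth and reports, for each clinical feature (rising slope, area
#' under the contraction, global maximum, average force, muscle relaxation),
#' the MAE, signed mean error, standard deviation of the error and RMSPE of
#' the extracted value against the true value. Recordings on which the
#' extractor fails (e.g. rest traces with no contraction) are counted and
#' excluded from the statistics.
#'
#' @param dataset a list whose elements each contain `recording` (a
#'   [recording()]) and `truth` (a list with the true feature values, as
#'   produced by [gen_mvc()]).
#' @param extractor a function `recording -> pfm_features`; defaults to
#'   [extract_features()].
#' @return A list with `table` (data frame: feature, mae, mean_error,
#'   sd_error, rmspe, n), `n_failed`, and `failures` (indices).
#' @export
validate_extraction <- function(dataset, extractor = extract_features) {
  truths <- list(); ests <- list(); failed <- integer(0)
  for (i in seq_along(dataset)) {
    item <- dataset[[i]]
    fx <- tryCatch(extractor(item$recording), error = function(e) NULL)
    if (is.null(fx)) { failed <- c(failed, i); next }
    truths[[length(truths) + 1L]] <- item$truth$features
    ests[[length(ests) + 1L]] <- fx
  }
  if (length(ests) == 0L) stop_parameter("extractor failed on every recording")
  rows <- lapply(.validation_features, function(f) {
    y  <- vapply(truths, function(tr) as.numeric(tr[[f]]), numeric(1))
    yp <- vapply(ests,   function(es) as.numeric(es[[f]]), numeric(1))
    st <- error_stats(y, yp)
    data.frame(feature = f, mae = st$mae, mean_error = st$mean_error,
               sd_error = st$sd_error, rmspe = st$rmspe, n = st$n,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), n_failed = length(failed), failures = failed)
}
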