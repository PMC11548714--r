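# Rule-based trapezoid modelling of maximal voluntary contractions (MVC).
#
# An MVC force trace is approximated by five linear segments delimited by the
# corner points A (trace start), B (contraction onset), C (plateau start),
# D (plateau end) and E (contraction end). Corners are located on the first
# derivative of the baseline-subtracted signal: B and E by a descending
# threshold ladder, C and D by zero crossings.

#' Subtract the baseline mean from a signal
#'
#' @param samples numeric force signal (N).
#' @param window integer indices of the baseline window (e.g. `1:10`).
#' @return The baseline-subtracted samples, with the window mean attached as
#'   attribute `"baseline_mean"` (needed later for the relaxation feature).
#' @export
subtract_baseline <- function(samples, window) {
  if (length(window) == 0L) stop_parameter("baseline window must be non-empty")
  if (any(window < 1L) || any(window > length(samples)))
    stop_parameter("baseline window outside the signal")
  m <- mean(samples[window])
  structure(samples - m, baseline_mean = m)
}

#' First derivative of a sampled signal
#'
#' First differences scaled by the sampling rate; output element `i`
#' corresponds to the interval between samples `i` and `i+1` (left endpoint
#' convention), so the output is one shorter than the input.
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @return Numeric vector of length `length(samples) - 1` in N/s.
#' @export
derivative <- function(samples, fs) {
  if (length(samples) < 2L) stop_parameter("need at least 2 samples")
  diff(samples) * fs
}

#' Detect the contraction onset (first rise) in a derivative signal
#'
#' Walks a descending ladder of thresholds: for the first threshold that is
#' exceeded anywhere, returns the index of the first derivative sample
#' exceeding it. Several thresholds are needed because no single absolute
#' value suits both weak and strong contractions.
#'
#' @param deriv numeric derivative signal (N/s).
#' @param thresholds strictly descending numeric vector of thresholds (N/s).
#' @return Index (1-based) of the first sample above the successful threshold.
#' @export
detect_first_rise <- function(deriv, thresholds) {
  check_thresholds(thresholds)
  for (thr in thresholds) {
    idx <- which(deriv > thr)
    if (length(idx)) return(idx[1L])
  }
  stop_detection("no rise found")
}

check_thresholds <- function(thresholds) {
  if (length(thresholds) == 0L) stop_parameter("thresholds must be non-empty")
  if (length(thresholds) > 1L && any(diff(thresholds) >= 0))
    stop_parameter("thresholds must be strictly descending")
  invisible(thresholds)
}

#' Detect the contraction end (last fall) in a derivative signal
#'
#' The derivative is reversed in time and mirrored about the x-axis, which
#' turns the last fall into a first rise; the rise detector is applied and the
#' hit is mapped back to the original orientation.
#'
#' @inheritParams detect_first_rise
#' @return Index (1-based) of the last falling derivative sample.
#' @export
detect_last_fall <- function(deriv, thresholds) {
  check_thresholds(thresholds)
  g <- -rev(deriv)
  j <- tryCatch(detect_first_rise(g, thresholds),
                error = function(e) stop_detection("no fall found"))
  length(deriv) - j + 1L
}

#' Detect the first maximum after the contraction onset (plateau start)
#'
#' Finds the first zero crossing of the derivative after `rise_idx`: the first
#' index where the derivative is no longer positive after having been positive
#' — the force maximum that opens the plateau (point C).
#'
#' @param deriv numeric derivative signal (typically smoothed).
#' @param rise_idx index returned by [detect_first_rise()].
#' @return Index of the crossing (first sample of the non-positive region).
#' @export
detect_first_max_after <- function(deriv, rise_idx) {
  m <- length(deriv)
  if (rise_idx < 1L || rise_idx > m) stop_parameter("rise_idx outside derivative")
  i <- rise_idx + 1L
  while (i <= m) {
    if (deriv[i] <= 0 && deriv[i - 1L] > 0) return(i)
    i <- i + 1L
  }
  stop_detection("no maximum found after the first rise")
}

#' Detect the last maximum before the contraction end (plateau end)
#'
#' Finds the last zero crossing of the derivative before `fall_idx`: the last
#' index where the derivative turns negative after having been non-negative —
#' the force maximum that closes the plateau (point D).
#'
#' @param deriv numeric derivative signal (typically smoothed).
#' @param fall_idx index returned by [detect_last_fall()].
#' @return Index of the crossing (first sample of the negative region).
#' @export
detect_last_max_before <- function(deriv, fall_idx) {
  if (fall_idx < 2L || fall_idx > length(deriv)) stop_parameter("fall_idx outside derivative")
  cand <- which(deriv[2:(fall_idx - 1L)] < 0 & deriv[1:(fall_idx - 2L)] >= 0) + 1L
  if (length(cand) == 0L) stop_detection("no maximum found before the last fall")
  cand[length(cand)]
}

# Default descending threshold ladder: fractions of the relevant signed
# extremum of the smoothed derivative, clamped from below by an absolute floor
# so that traces with no drastic rise at all (rest, push) fail detection
# instead of self-triggering on their own noise.
default_thresholds <- function(peak, fracs = c(0.5, 0.25, 0.1, 0.05), floor_abs = 0.6) {
  th <- fracs * peak
  th <- th[th >= floor_abs]
  if (length(th) == 0L) th <- floor_abs
  th
}

#' Fit the five-segment trapezoid model to an MVC recording
#'
#' Pipeline: subtract the baseline mean (default window: first 0.5 s), take
#' the first derivative, smooth it with a centred moving average (default
#' width 5 samples), then locate the four corners: B via
#' [detect_first_rise()] and E via [detect_last_fall()] on threshold ladders
#' derived from the positive and negative extrema of the smoothed derivative,
#' and C/D via the zero-crossing detectors, compensating the moving-average
#' group delay of `(width-1)/2` samples. Segment lines are chords through the
#' signal values at the corner points, which keeps the piecewise model
#' continuous with its eight degrees of freedom. On a noiseless on-grid
#' trapezoid all four corners are recovered exactly and the fitted trace
#' equals the input.
#'
#' @param rec a [recording()] of an MVC task (at least 20 samples).
#' @param thresholds optional explicit descending threshold ladder (N/s) used
#'   for both rise and fall; by default ladders are fractions
#'   `c(0.5, 0.25, 0.1, 0.05)` of the signed derivative extrema.
#' @param baseline_window_s baseline window length in seconds (default 0.5).
#' @param smooth_width odd moving-average width for the derivative (default 5).
#' @param threshold_fracs fractions for the default ladder.
#' @param min_slope absolute threshold floor in N/s (default 0.6); traces whose
#'   smoothed derivative never reaches it raise a detection error.
#' @param refine refine the detected corners by intersecting least-squares
#'   segment lines (default `TRUE`); exact on noiseless data and sub-sample
#'   accurate under noise.
#' @return An object of class `pfm_trapezoid_fit` with corner indices
#'   `idx_A` .. `idx_E`, `segment_params` (4 x 2 matrix of slope, intercept
#'   in N/s and N), `fitted` (piecewise-linear samples over `[A, E]`), the
#'   baseline-subtracted `samples`, `baseline_pre_mean`, `fs`, `smooth_width`.
#' @export
fit_trapezoid <- function(rec, thresholds = NULL, baseline_window_s = 0.5,
                          smooth_width = 5L, threshold_fracs = c(0.5, 0.25, 0.1, 0.05),
                          min_slope = 0.6, refine = TRUE) {
  stopifnot(inherits(rec, "pfm_recording"))
  n <- length(rec$samples)
  if (n < 20L) stop_parameter("recording too short to fit a trapezoid (need >= 20 samples)")
  fs <- rec$fs
  bw <- seq_len(max(1L, round(baseline_window_s * fs)))
  x <- subtract_baseline(rec$samples, bw)
  base_pre <- attr(x, "baseline_mean")
  x <- as.numeric(x)

  d <- derivative(x, fs)
  sm <- smooth_ma(d, smooth_width)
  g <- (smooth_width - 1L) %/% 2L
  if (g > 0L && length(sm) > 2L * g) {
    # the first/last half-windows average replicated edge differences and are
    # noise-dominated; corners cannot lie there, so exclude them from search
    sm[seq_len(g)] <- 0
    sm[(length(sm) - g + 1L):length(sm)] <- 0
  }

  th_rise <- thresholds %||% default_thresholds(max(sm), threshold_fracs, min_slope)
  th_fall <- thresholds %||% default_thresholds(max(-sm), threshold_fracs, min_slope)

  on <- tryCatch(confirmed_first_rise(sm, th_rise),
                 error = function(e) stop_detection(sprintf("onset (B): %s", conditionMessage(e))))
  B <- on$idx; thr_r <- on$thr
  off <- tryCatch(confirmed_first_rise(-rev(sm), th_fall),
                  error = function(e) stop_detection(sprintf("end (E): %s", conditionMessage(e))))
  Ed <- length(sm) - off$idx + 1L; thr_f <- off$thr
  E <- Ed + 1L
  Cc <- confirmed_plateau_start(sm, B, thr_r)
  Cc <- max(B + 1L, Cc - g)
  Dd <- confirmed_plateau_end(sm, Ed, thr_f)
  Dd <- min(E - 1L, Dd + g)

  if (!(1L <= B && B < Cc && Cc <= Dd && Dd < E && E <= n))
    stop_fit(sprintf("corner ordering violated: B=%d C=%d D=%d E=%d (n=%d)", B, Cc, Dd, E, n))

  if (refine) {
    rc <- refine_corners(x, fs, B, Cc, Dd, E, g)
    B <- rc[1L]; Cc <- rc[2L]; Dd <- rc[3L]; E <- rc[4L]
  }
  build_trapezoid_fit(x, fs, 1L, B, Cc, Dd, E, base_pre, smooth_width)
}

# Threshold-ladder search with a sustained-rise confirmation: a candidate
# exceedance counts only when the smoothed derivative stays high just after it
# (mean of the next five samples above half the threshold), so a lone noise
# spike in the baseline cannot pass for the contraction onset. Reduces to the
# plain first exceedance on noiseless data.
confirmed_first_rise <- function(sm, thresholds) {
  m <- length(sm)
  for (thr in thresholds) {
    for (k in which(sm > thr)) {
      if (mean(sm[k:min(k + 4L, m)]) > 0.5 * thr) return(list(idx = k, thr = thr))
    }
  }
  stop_detection("no rise found")
}

# Zero-crossing search with a sustained-sign confirmation: a candidate plateau
# start is accepted only when the smoothed derivative stays near zero after it
# (a lone noise dip in the middle of the rise does not), and symmetrically a
# candidate plateau end must be preceded by a near-zero stretch. Both reduce
# to the plain first/last crossing on noiseless data.
confirmed_plateau_start <- function(sm, rise_idx, thr) {
  m <- length(sm)
  k <- rise_idx
  repeat {
    k <- tryCatch(detect_first_max_after(sm, k),
                  error = function(e) stop_detection(sprintf("plateau start (C): %s",
                                                             conditionMessage(e))))
    if (mean(sm[k:min(k + 4L, m)]) <= 0.25 * thr) return(k)
    if (k >= m) stop_detection("plateau start (C): no confirmed maximum")
  }
}

confirmed_plateau_end <- function(sm, fall_idx, thr) {
  cand <- which(sm[2:(fall_idx - 1L)] < 0 & sm[1:(fall_idx - 2L)] >= 0) + 1L
  if (length(cand) == 0L) stop_detection("plateau end (D): no maximum before the last fall")
  for (i in rev(cand)) {
    if (mean(sm[max(i - 5L, 1L):max(i - 1L, 1L)]) >= -0.25 * thr) return(i)
  }
  cand[length(cand)]
}

# closed-form least-squares line through samples idx (time in seconds)
ls_line <- function(x, fs, idx) {
  idx <- idx[idx >= 1L & idx <= length(x)]
  if (length(idx) < 1L) return(NULL)
  if (length(idx) == 1L) return(c(0, x[idx]))
  ti <- (idx - 1L) / fs
  yi <- x[idx]
  m <- sum((ti - mean(ti)) * (yi - mean(yi))) / sum((ti - mean(ti))^2)
  c(m, mean(yi) - m * mean(ti))
}

intersect_lines <- function(l1, l2) {
  if (is.null(l1) || is.null(l2)) return(NA_real_)
  dm <- l1[1L] - l2[1L]
  if (!is.finite(dm) || abs(dm) < 1e-9) return(NA_real_)
  (l2[2L] - l1[2L]) / dm
}

# Refine corner indices by intersecting least-squares lines fitted to the
# interior of each segment (guard-trimmed by the smoothing half-width). The
# initial detector corners choose the segment windows; the intersections then
# locate the corners with sub-sample precision, which is exact on noiseless
# piecewise-linear data and robust to +/- a few samples of detector error.
refine_corners <- function(x, fs, B, Cc, Dd, E, g) {
  n <- length(x)
  interior <- function(i1, i2) if (i2 - i1 - 2L * g >= 1L) (i1 + g):(i2 - g) else i1:i2
  l_base <- ls_line(x, fs, 1L:max(B - g, 2L))
  l_base[1L] <- 0  # the pre-contraction baseline is flat by model
  l_rise <- ls_line(x, fs, interior(B, Cc))
  l_plat <- ls_line(x, fs, interior(Cc, Dd))
  l_fall <- ls_line(x, fs, interior(Dd, E))
  post_idx <- min(E + g, n):n
  l_post <- c(0, mean(x[post_idx]))

  to_idx <- function(t, fallback, lo, hi) {
    i <- if (is.finite(t)) as.integer(round(t * fs)) + 1L else fallback
    # the segment windows are only trustworthy near the detector corners:
    # cap the refinement shift so a contaminated line cannot drag a corner far
    i <- min(max(i, fallback - 8L), fallback + 8L)
    min(max(i, lo), hi)
  }
  nB <- to_idx(intersect_lines(l_base, l_rise), B, 2L, n - 3L)
  nC <- to_idx(intersect_lines(l_rise, l_plat), Cc, nB + 1L, n - 2L)
  nD <- to_idx(intersect_lines(l_plat, l_fall), Dd, nC, n - 1L)
  nE <- to_idx(intersect_lines(l_fall, l_post), E, nD + 1L, n)
  if (!(nB < nC && nC <= nD && nD < nE)) return(c(B, Cc, Dd, E))
  c(nB, nC, nD, nE)
}

# Assemble the fit object from corner indices: chords through the corner
# sample values, continuity by construction.
build_trapezoid_fit <- function(x, fs, A, B, Cc, Dd, E, base_pre, smooth_width) {
  tt <- (c(A, B, Cc, Dd, E) - 1L) / fs
  vv <- x[c(A, B, Cc, Dd, E)]
  seg <- t(vapply(1:4, function(k) {
    m <- (vv[k + 1L] - vv[k]) / (tt[k + 1L] - tt[k])
    c(slope = m, intercept = vv[k] - m * tt[k])
  }, numeric(2)))
  rownames(seg) <- c("baseline", "rise", "plateau", "fall")
  m_r <- seg["rise", 1L]; m_f <- seg["fall", 1L]
  if (!(m_r > 0)) stop_fit("rising slope not positive")
  if (!(m_f < 0)) stop_fit("falling slope not negative")

  idx <- A:E
  t_idx <- (idx - 1L) / fs
  segment_of <- findInterval(t_idx, tt, rightmost.closed = TRUE)
  segment_of[segment_of < 1L] <- 1L; segment_of[segment_of > 4L] <- 4L
  fitted <- seg[segment_of, 1L] * t_idx + seg[segment_of, 2L]

  structure(list(idx_A = A, idx_B = B, idx_C = Cc, idx_D = Dd, idx_E = E,
                 segment_params = seg, fitted = fitted, samples = x,
                 baseline_pre_mean = base_pre, fs = fs,
                 smooth_width = as.integer(smooth_width)),
            class = "pfm_trapezoid_fit")
}

#' @export
print.pfm_trapezoid_fit <- function(x, ...) {
  cat(sprintf("<trapezoid fit> corners A=%d B=%d C=%d D=%d E=%d @ %g Hz\n",
              x$idx_A, x$idx_B, x$idx_C, x$idx_D, x$idx_E, x$fs))
  cat(sprintf("  rise %.3f N/s, fall %.3f N/s\n",
              x$segment_params["rise", 1], x$segment_params["fall", 1]))
  invisible(x)
}

#' Fit the trapezoid model by constrained least squares
#'
#' Alternative to the rule-based [fit_trapezoid()]: directly minimises the
#' squared error between the signal and the eight-parameter piecewise-linear
#' model (four corner times, four corner force levels), under the constraints
#' that corners are ordered and that the rising slope is positive and the
#' falling slope negative. Optimisation is Nelder-Mead with constraint
#' penalties and a coarse data-driven start.
#'
#' @inheritParams fit_trapezoid
#' @param maxit maximum optimiser iterations per restart.
#' @return A `pfm_trapezoid_fit` (corner indices rounded to the sample grid).
#' @export
fit_trapezoid_lsq <- function(rec, baseline_window_s = 0.5, smooth_width = 5L,
                              maxit = 2000L) {
  stopifnot(inherits(rec, "pfm_recording"))
  n <- length(rec$samples)
  if (n < 20L) stop_parameter("recording too short (need >= 20 samples)")
  fs <- rec$fs
  bw <- seq_len(max(1L, round(baseline_window_s * fs)))
  x <- subtract_baseline(rec$samples, bw)
  base_pre <- attr(x, "baseline_mean")
  x <- as.numeric(x)
  tt <- (seq_len(n) - 1L) / fs
  xs <- smooth_ma(x, smooth_width)
  pk <- max(xs)
  if (pk < 10 * (sd(x - xs) + 1e-12) || pk <= 0)
    stop_fit("no contraction structure to fit (flat signal)")

  model_eval <- function(p, t) {
    tb <- p[1]; tc <- p[2]; td <- p[3]; te <- p[4]
    y0 <- p[5]; yc <- p[6]; yd <- p[7]; ye <- p[8]
    y <- numeric(length(t))
    y[t < tb] <- y0
    i <- t >= tb & t < tc; y[i] <- y0 + (yc - y0) * (t[i] - tb) / (tc - tb)
    i <- t >= tc & t < td; y[i] <- yc + (yd - yc) * (t[i] - tc) / (td - tc)
    i <- t >= td & t <= te; y[i] <- yd + (ye - yd) * (t[i] - td) / (te - td)
    y[t > te] <- ye
    y
  }
  obj <- function(p) {
    tb <- p[1]; tc <- p[2]; td <- p[3]; te <- p[4]
    y0 <- p[5]; yc <- p[6]; yd <- p[7]; ye <- p[8]
    gap <- 1 / fs
    viol <- max(0, tb - (tc - gap)) + max(0, tc - td) + max(0, td - (te - gap)) +
      max(0, -tb) + max(0, te - tt[n]) +
      max(0, y0 - yc + 1e-6) + max(0, ye - yd + 1e-6)
    if (viol > 0) return(1e9 * (1 + viol))
    sum((x - model_eval(p, tt))^2)
  }
  above <- function(f) {
    i <- which(xs > f * pk)
    c(tt[i[1L]], tt[i[length(i)]])
  }
  lo <- above(0.25); hi <- above(0.75)
  p0 <- c(lo[1], hi[1], hi[2], lo[2], 0, pk, pk, mean(x[max(1, n - 9):n]))
  fit1 <- optim(p0, obj, method = "Nelder-Mead", control = list(maxit = maxit))
  fit2 <- optim(fit1$par, obj, method = "Nelder-Mead", control = list(maxit = maxit))
  if (!is.finite(fit2$value) || fit2$value >= 1e9)
    stop_fit("least-squares trapezoid fit did not converge")
  p <- fit2$par
  ij <- pmin(pmax(round(p[1:4] * fs) + 1L, c(2L, 3L, 3L, 4L)), c(n - 3L, n - 2L, n - 2L, n - 1L))
  B <- ij[1]; Cc <- max(ij[2], B + 1L); Dd <- max(ij[3], Cc); E <- max(ij[4], Dd + 1L)
  if (!(B < Cc && Cc <= Dd && Dd < E && E <= n)) stop_fit("optimised corners unordered")
  build_trapezoid_fit(x, fs, 1L, B, Cc, Dd, E, base_pre, smooth_width)
}

#' Clinical features of a maximal contraction
#'
#' Computes the seven features used to rate a maximal PFM contraction from a
#' trapezoid fit:
#' \describe{
#'   \item{rising_slope}{slope of the B–C segment (N/s), least-squares over the
#'     segment samples (guard-trimmed by the smoothing half-width when enough
#'     samples remain) — identical to the two-point chord on noiseless data.}
#'   \item{falling_slope}{same for the D–E segment (N/s, negative).}
#'   \item{auc}{area under the contraction between B and E by the composite
#'     trapezoidal rule (N·s), exact for piecewise-linear on-grid signals.}
#'   \item{f_max}{global maximum force over \[A, E\] (N), taken on the
#'     smoothed signal so a single noise spike cannot set it; first index wins
#'     ties.}
#'   \item{f_avg}{arithmetic mean of the forces on \[B, E\] (N).}
#'   \item{t_c}{contraction time `(idx_E - idx_B)/fs` (s).}
#'   \item{relaxation}{post- minus pre-contraction baseline mean (N); 0 for a
#'     perfectly relaxing signal.}
#' }
#' The pre-contraction baseline average `f_ab` is also reported.
#'
#' @param fit a `pfm_trapezoid_fit`.
#' @param samples baseline-subtracted samples (defaults to those in `fit`).
#' @param fs sampling rate (defaults to `fit$fs`).
#' @param baseline_pre_mean,baseline_post_mean raw-signal means over the pre-
#'   and post-contraction baseline windows.
#' @return An object of class `pfm_features` (a named list).
#' @export
compute_features <- function(fit, samples = fit$samples, fs = fit$fs,
                             baseline_pre_mean = fit$baseline_pre_mean,
                             baseline_post_mean = baseline_pre_mean) {
  stopifnot(inherits(fit, "pfm_trapezoid_fit"))
  B <- fit$idx_B; Cc <- fit$idx_C; Dd <- fit$idx_D; E <- fit$idx_E; A <- fit$idx_A
  g <- (fit$smooth_width - 1L) %/% 2L

  seg_slope <- function(i1, i2) {
    if (i2 - i1 + 1L - 2L * g >= 4L) { i1 <- i1 + g; i2 <- i2 - g }
    ti <- (i1:i2 - 1L) / fs
    yi <- samples[i1:i2]
    sum((ti - mean(ti)) * (yi - mean(yi))) / sum((ti - mean(ti))^2)
  }
  m_r <- seg_slope(B, Cc)
  m_f <- seg_slope(Dd, E)

  xe <- samples[B:E]
  auc <- sum(xe[-length(xe)] + xe[-1L]) / (2 * fs)
  sm <- smooth_ma(samples, fit$smooth_width)
  f_max <- max(sm[A:E])
  f_avg <- mean(xe)
  t_c <- (E - B) / fs
  structure(list(
    rising_slope = m_r, falling_slope = m_f, auc = auc, f_max = f_max,
    f_avg = f_avg, t_c = t_c,
    relaxation = baseline_post_mean - baseline_pre_mean,
    f_ab = baseline_pre_mean,
    idx_B = B, idx_C = Cc, idx_D = Dd, idx_E = E
  ), class = "pfm_features")
}

#' @export
print.pfm_features <- function(x, ...) {
  cat(sprintf(paste0("<contraction features> rise %.3f N/s  fall %.3f N/s  AUC %.2f N.s\n",
                     "  Fmax %.2f N  Favg %.2f N  Tc %.2f s  relaxation %.3f N\n"),
              x$rising_slope, x$falling_slope, x$auc, x$f_max, x$f_avg, x$t_c, x$relaxation))
  invisible(x)
}

#' Extract contraction features from a recording in one call
#'
#' Convenience wrapper: baseline windows (first/last `baseline_window_s`
#' seconds), [fit_trapezoid()], then [compute_features()].
#'
#' @inheritParams fit_trapezoid
#' @return A `pfm_features` object with the fit attached as attribute `"fit"`.
#' @export
extract_features <- function(rec, thresholds = NULL, baseline_window_s = 0.5,
                             smooth_width = 5L, min_slope = 0.6) {
  n <- length(rec$samples)
  k <- max(1L, round(baseline_window_s * rec$fs))
  base_post <- mean(rec$samples[(n - k + 1L):n])
  fit <- fit_trapezoid(rec, thresholds = thresholds,
                       baseline_window_s = baseline_window_s,
                       smooth_width = smooth_width, min_slope = min_slope)
  fx <- compute_features(fit, baseline_post_mean = base_post)
  attr(fx, "fit") <- fit
  fx
}

# Columns normalized for rating/classification, in canonical order.
.feature_cols <- c("rising_slope", "falling_slope", "auc", "f_max", "f_avg",
                   "t_c", "relaxation")

#' Min-max normalise a table of contraction features
#'
#' Scales each feature to \[0, 1\] over the table. The falling slope is scaled
#' on its magnitude (so 1 = steepest descent) and the relaxation on its
#' magnitude with the direction inverted (so 1 = most complete relaxation).
#' The bounds are returned so unseen rows can be mapped with
#' [apply_normalization()] (values clipped to \[0, 1\]). A feature constant
#' across rows carries no information and is set to 0.5 with a warning.
#'
#' @param df data frame with the columns
#'   `rising_slope, falling_slope, auc, f_max, f_avg, t_c, relaxation`
#'   (e.g. from [features_to_df()]).
#' @return A list: `table` (df with added `*_norm` columns) and `bounds`.
#' @export
normalize_features <- function(df) {
  if (!is.data.frame(df) || nrow(df) < 2L)
    stop_parameter("need at least 2 feature rows to normalize")
  missing <- setdiff(.feature_cols, names(df))
  if (length(missing)) stop_parameter(paste("missing feature column:", missing[1L]))
  raw <- transform_features(df)
  mins <- vapply(raw, min, numeric(1))
  maxs <- vapply(raw, max, numeric(1))
  bounds <- list(mins = mins, maxs = maxs)
  norm <- scale_features(raw, bounds, warn_constant = TRUE)
  out <- df
  for (f in .feature_cols) out[[paste0(f, "_norm")]] <- norm[[f]]
  list(table = out, bounds = bounds)
}

# magnitude transforms applied before min-max scaling
transform_features <- function(df) {
  raw <- df[.feature_cols]
  raw$falling_slope <- abs(raw$falling_slope)
  raw$relaxation <- abs(raw$relaxation)
  raw
}

scale_features <- function(raw, bounds, warn_constant = FALSE) {
  norm <- raw
  for (f in .feature_cols) {
    rng <- bounds$maxs[[f]] - bounds$mins[[f]]
    if (rng <= 0) {
      if (warn_constant) warning(sprintf("feature '%s' constant across rows; normalized to 0.5", f))
      norm[[f]] <- rep(0.5, nrow(raw))
    } else {
      norm[[f]] <- pmin(1, pmax(0, (raw[[f]] - bounds$mins[[f]]) / rng))
    }
    if (f == "relaxation") norm[[f]] <- 1 - norm[[f]]  # 1 = most complete relaxation
  }
  norm
}

#' Apply stored normalisation bounds to new feature rows
#'
#' @param bounds bounds from [normalize_features()].
#' @param df data frame of raw features.
#' @return `df` with `*_norm` columns added, values clipped to \[0, 1\].
#' @export
apply_normalization <- function(bounds, df) {
  norm <- scale_features(transform_features(df), bounds)
  for (f in .feature_cols) df[[paste0(f, "_norm")]] <- norm[[f]]
  df
}

#' Convert a list of feature objects to a data frame
#'
#' @param fx_list list of `pfm_features`.
#' @return Data frame with one row per element.
#' @export
features_to_df <- function(fx_list) {
  do.call(rbind, lapply(fx_list, function(fx) {
    as.data.frame(unclass(fx)[c(.feature_cols, "f_ab", "idx_B", "idx_C", "idx_D", "idx_E")])
  }))
}

#' Construct overall-rating weights
#'
#' @param c1,c2,c3,c4,c5 non-negative weights for peak force, contraction
#'   time, average force, slopes, and relaxation; must sum to 1 so the rating
#'   lands in \[0, 100\].
#' @return A named numeric vector of class `pfm_rating_weights`.
#' @export
rating_weights <- function(c1 = 0.2, c2 = 0.2, c3 = 0.2, c4 = 0.2, c5 = 0.2) {
  w <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
  if (any(w < 0)) stop_parameter("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8) stop_parameter("weights must sum to 1")
  structure(w, class = "pfm_rating_weights")
}

#' Overall contraction rating
#'
#' Weighted combination of the normalised features, in percent:
#' \deqn{(c_1 \hat{\Delta F}_{max} + c_2 \hat T_c + c_3 \hat{\bar F}_c +
#'   c_4 \tfrac{\hat m_r + \hat m_f}{2} + c_5 \hat{\Delta F}_{f-i}) \times 100}
#' where hats denote normalised values (relaxation already inverted so that 1
#' is complete relaxation). Linear in every feature and bounded in \[0, 100\].
#'
#' @param normalized a named list/vector or one-row data frame with the
#'   normalised features `f_max, t_c, f_avg, rising_slope, falling_slope,
#'   relaxation` (accepts `*_norm` column names).
#' @param weights a [rating_weights()] object (default: equal weights 0.2).
#' @return The rating in percent.
#' @export
overall_rating <- function(normalized, weights = rating_weights()) {
  if (!inherits(weights, "pfm_rating_weights")) weights <- do.call(rating_weights, as.list(weights))
  get1 <- function(f) {
    v <- normalized[[paste0(f, "_norm")]] %||% normalized[[f]]
    if (is.null(v) || is.na(v[1L])) stop_parameter(sprintf("missing normalized feature '%s'", f))
    as.numeric(v[1L])
  }
  vals <- vapply(.feature_cols, get1, numeric(1))
  unname((weights[["c1"]] * vals[["f_max"]] +
          weights[["c2"]] * vals[["t_c"]] +
          weights[["c3"]] * vals[["f_avg"]] +
          weights[["c4"]] * (vals[["rising_slope"]] + vals[["falling_slope"]]) / 2 +
          weights[["c5"]] * vals[["relaxation"]]) * 100)
}
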