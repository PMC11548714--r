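# Down-sampling of legacy 1024 Hz recordings to 20 Hz with fidelity metrics.

# Direct-form II transposed IIR filter with initial state zi (length order).
iir_filter <- function(b, a, x, zi = NULL) {
  nord <- length(a) - 1L
  if (is.null(zi)) zi <- numeric(nord)
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (nord > 1L)
      for (k in seq_len(nord - 1L))
        z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
    z[nord] <- b[nord + 1L] * xi - a[nord + 1L] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-step input (matches scipy lfilter_zi):
# starting the filter at zi * x[1] removes the start-up transient.
iir_zi <- function(b, a) {
  n <- length(a) - 1L
  A <- rbind(-a[2:(n + 1L)], cbind(diag(1, n - 1L), numeric(n - 1L)))
  B <- b[2:(n + 1L)] - a[2:(n + 1L)] * b[1L]
  solve(diag(1, n) - t(A), B)
}

# Zero-phase (forward-backward) filtering with odd-reflection padding and
# steady-state initial conditions, so constants pass unchanged and edges carry
# no transient.
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  nord <- length(a) - 1L
  padlen <- min(n - 1L, 3L * (nord + 1L))
  if (padlen < 1L) stop_parameter("signal too short for stable filtering")
  front <- 2 * x[1L] - x[(padlen + 1L):2L]
  back  <- 2 * x[n]  - x[(n - 1L):(n - padlen)]
  ext <- c(front, x, back)
  zi <- iir_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter (via [signal::butter()]) and applies
#' it forward and backward, so the net magnitude response is the squared
#' Butterworth response and the phase response is zero: filtering does not lag
#' the signal, which matters because corner times feed the trapezoid feature
#' extractor downstream.
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz); must satisfy `0 < cutoff < fs/2`.
#' @param order filter order (default 4).
#' @return The filtered signal, same length.
#' @export
butterworth_lowpass <- function(samples, fs, cutoff, order = 4L) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    stop_parameter("cutoff must satisfy 0 < cutoff < fs/2")
  if (!is_count(order) || order < 1) stop_parameter("order must be a positive integer")
  if (length(samples) <= 3L * order) stop_parameter("signal too short for stable filtering")
  bt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_zp(bt$b, bt$a, as.numeric(samples))
}

#' Dominant frequencies of a signal
#'
#' Magnitudes of the discrete Fourier transform of the mean-removed signal
#' (no window, raw bins, DC excluded); returns the frequencies of the `k`
#' largest magnitudes in descending magnitude order.
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @param k number of frequencies to return.
#' @return Numeric vector of `k` frequencies (Hz).
#' @export
dominant_frequencies <- function(samples, fs, k = 3L) {
  n <- length(samples)
  if (!is_count(k) || k < 1) stop_parameter("k must be a positive integer")
  if (n < 2L * k) stop_parameter("signal too short for k dominant frequencies")
  spec <- Mod(fft(samples - mean(samples)))
  nbin <- floor(n / 2)                  # positive-frequency bins, DC excluded
  if (k > nbin) stop_parameter("k exceeds available frequency bins")
  mag <- spec[2:(nbin + 1L)]
  if (all(mag < 1e-12 * max(1, max(abs(samples)))))
    stop_parameter("signal has no spectral content after DC exclusion")
  ord <- order(mag, decreasing = TRUE)[seq_len(k)]
  ord * fs / n
}

#' Down-sample a recording and quantify reconstruction fidelity
#'
#' The pipeline follows the decimation recipe for legacy 1024 Hz recordings:
#' a fourth-order Butterworth low-pass at half the target rate (the new
#' Nyquist frequency) removes content the lower rate cannot represent, the
#' filtered signal is then sampled at the target instants (non-integer
#' decimation ratios are handled by linear interpolation between neighbouring
#' filtered samples), and fidelity is assessed by reconstructing the signal on
#' the original support with a zero-order hold (phase-centred: each sample is
#' held over the half-sample interval around its instant) followed by the same
#' low-pass smoothing. [rmspe()] compares original against reconstructed
#' signal, and the top-`k` dominant frequencies of the original and
#' down-sampled signals are compared the same way.
#'
#' @param rec a [recording()].
#' @param fs_out target sampling rate (Hz), < `rec$fs`.
#' @param order Butterworth order (default 4).
#' @param k number of dominant frequencies to compare (default 3).
#' @return A list of class `pfm_downsample_result`: `downsampled` and
#'   `reconstructed` recordings, `rmspe_signal`, `dominant_freqs_original`,
#'   `dominant_freqs_downsampled`, `rmspe_freqs`.
#' @export
downsample <- function(rec, fs_out, order = 4L, k = 3L) {
  stopifnot(inherits(rec, "pfm_recording"))
  if (!is.numeric(fs_out) || fs_out <= 0 || fs_out >= rec$fs)
    stop_parameter("fs_out must be positive and below the recording rate")
  x <- rec$samples
  n <- length(x)
  cutoff <- fs_out / 2
  xf <- butterworth_lowpass(x, rec$fs, cutoff, order)

  t_src <- (seq_len(n) - 1L) / rec$fs
  n_out <- floor(t_src[n] * fs_out) + 1L
  t_out <- (seq_len(n_out) - 1L) / fs_out
  y <- approx(t_src, xf, xout = t_out)$y

  # nearest-sample (phase-centred) zero-order hold back onto the source grid
  idx <- pmin(pmax(round(t_src * fs_out) + 1L, 1L), n_out)
  zoh <- y[idx]
  recon <- butterworth_lowpass(zoh, rec$fs, cutoff, order)

  # constant traces have no spectrum after DC exclusion; report NA frequencies
  f_orig <- tryCatch(dominant_frequencies(x, rec$fs, k), error = function(e) rep(NA_real_, k))
  f_down <- tryCatch(dominant_frequencies(y, fs_out, k), error = function(e) rep(NA_real_, k))

  structure(list(
    downsampled = recording(y, fs = fs_out, task = rec$task,
                            subject_id = rec$subject_id, session = rec$session,
                            mos = rec$mos, buttock_movement = rec$buttock_movement),
    reconstructed = recording(recon, fs = rec$fs, task = rec$task,
                              subject_id = rec$subject_id, session = rec$session),
    rmspe_signal = if (max(abs(x)) == 0) 0 else rmspe(x, recon),
    dominant_freqs_original = f_orig,
    dominant_freqs_downsampled = f_down,
    rmspe_freqs = if (anyNA(f_orig) || anyNA(f_down)) NA_real_ else rmspe(f_orig, f_down)
  ), class = "pfm_downsample_result")
}

#' @export
print.pfm_downsample_result <- function(x, ...) {
  cat(sprintf("<downsample> %g Hz -> %g Hz  RMSPE(signal)=%.3f%%  RMSPE(freqs)=%.3f%%\n",
              x$reconstructed$fs, x$downsampled$fs, x$rmspe_signal, x$rmspe_freqs))
  cat("  dominant f (orig):", paste(signif(x$dominant_freqs_original, 4), collapse = ", "), "Hz\n")
  cat("  dominant f (down):", paste(signif(x$dominant_freqs_downsampled, 4), collapse = ", "), "Hz\n")
  invisible(x)
}
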