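# Shared fixtures, built in code.

# Noiseless on-grid trapezoid with explicit corner times (seconds).
clean_trapezoid <- function(tB = 2, tC = 4, tD = 12, tE = 14, plateau = 10,
                            duration = 16, fs = 20, offset = 0.5, residual = 0) {
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  i <- tt > tB & tt <= tC; x[i] <- plateau * (tt[i] - tB) / (tC - tB)
  x[tt > tC & tt <= tD] <- plateau
  i <- tt > tD & tt <= tE; x[i] <- plateau + (residual - plateau) * (tt[i] - tD) / (tE - tD)
  x[tt > tE] <- residual
  recording(offset + x, fs = fs, task = "mvc")
}

# Same geometry plus white noise, seeded.
noisy_trapezoid <- function(seed, sigma = 0.2, ...) {
  rec <- clean_trapezoid(...)
  withr::with_seed(seed, {
    rec$samples <- rec$samples + rnorm(length(rec$samples), 0, sigma)
  })
  rec
}

quiet_params <- function(...) generator_params(noise_sd = 0, sensor_noise_n = 0, ...)

expect_pfmqa_error <- function(expr, class) expect_error(expr, class = class)
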