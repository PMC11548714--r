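# Seeded generator of labeled synthetic dynamometric recordings.
#
# The generator emulates the signal-level statistics of the four dynamometric
# tasks: flat noisy rest baselines, 10 s approximately trapezoidal maximal
# contractions whose amplitude scales with the MOS grade and whose rise
# strategy varies (rapid vs gradual), short high-amplitude cough spikes, and
# slow low-amplitude push drifts. Every MVC carries analytic pre-noise ground
# truth (corner times and feature values) so extraction accuracy can be
# validated against it.

#' Default synthetic-generator parameters
#'
#' All force values in newtons, times in seconds, rates in hertz.
#' Key defaults: 20 Hz sampling; additive white Gaussian noise with sd 2% of
#' the plateau on MVCs and a 0.02 N sensor floor elsewhere; grade-to-peak-force
#' map with means (2, 6, 12, 20, 30) N for MOS 1..5 and sd 20% of the mean
#' (adjacent grades overlap, so a +/-1-class tolerance is meaningful); rise
#' times 0.25--2 s with "rapid" risers drawing from the short end of the
#' range; falls 0.5--1.5 s; an incomplete-relaxation residual of 15--35% of
#' the plateau after the contraction.
#'
#' @param ... overrides for any parameter.
#' @return A list of class `pfm_generator_params`.
#' @export
generator_params <- function(...) {
  p <- list(
    fs = 20,
    noise_sd = 0.02,                      # fraction of plateau (MVC noise)
    sensor_noise_n = 0.02,                # absolute noise floor (N), non-MVC tasks
    baseline_offset_range = c(0.2, 1.0),  # N
    mvc_duration = 10, rest_duration = 5, push_duration = 10,
    grade_amplitude_mean = c(2, 6, 12, 20, 30),  # N, MOS 1..5
    grade_amplitude_sd_frac = 0.2,
    rise_time_range = c(0.25, 2.0),       # rapid risers draw from the short end
    rapid_split = 0.3,                    # fraction of the range forming the short end
    strategy_mix = 0.5,                   # fraction of rapid risers
    fall_time_range = c(0.5, 1.5),
    pre_range = c(1, 2), post_range = c(1, 2),
    relaxation_residual_range = c(0.15, 0.35),  # fraction of plateau
    ripple_frac = 0,                      # optional plateau ripple amplitude
    cough_width_range = c(0.3, 0.5),
    cough_amp_range = c(5, 25),
    push_drift_range = c(0.02, 0.12),     # N/s
    amplitude_scale = 1, noise_scale = 1  # device presets
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop_parameter(paste("unknown generator parameter:", unknown[1L]))
  p <- modifyList(p, over)
  if (any(diff(p$grade_amplitude_mean) <= 0))
    stop_parameter("grade amplitude means must be strictly increasing")
  ranges <- c("baseline_offset_range", "rise_time_range", "fall_time_range",
              "cough_width_range", "relaxation_residual_range")
  for (r in ranges)
    if (any(p[[r]] < 0) || diff(p[[r]]) < 0) stop_parameter(paste("invalid range:", r))
  structure(p, class = "pfm_generator_params")
}

#' Parameters emulating a second dynamometer ("device B")
#'
#' Same protocol, shifted operating point: peak amplitudes scaled by 0.6 and
#' noise by 1.5, supporting cross-device generalization tests.
#'
#' @param base parameters to modify (default [generator_params()]).
#' @return A `pfm_generator_params`.
#' @export
device_b_params <- function(base = generator_params()) {
  base$amplitude_scale <- base$amplitude_scale * 0.6
  base$noise_scale <- base$noise_scale * 1.5
  base
}

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Generate one synthetic maximal voluntary contraction
#'
#' Baseline offset plus an on-grid trapezoid: flat pre-baseline, linear rise
#' to a plateau whose height is drawn from the grade's amplitude
#' distribution, linear fall to an incomplete-relaxation residual, flat tail;
#' additive Gaussian noise with sd `noise_sd` times the plateau. Corner times
#' are snapped to the sampling grid, and ground truth (corners, plateau, and
#' all feature values computed analytically from the pre-noise trace) is
#' recorded.
#'
#' @param grade MOS grade 1--5.
#' @param params a [generator_params()].
#' @param seed optional integer seed (otherwise the current RNG stream is used).
#' @return A list: `recording` (task `"mvc"`, `mos = grade`) and `truth`
#'   (corner times/indices, plateau force, `features`).
#' @export
gen_mvc <- function(grade, params = generator_params(), seed = NULL) {
  if (!is_count(grade) || grade < 1 || grade > 5) stop_parameter("grade must be an integer 1..5")
  fs <- params$fs
  dur <- params$mvc_duration
  if (min(params$pre_range) + min(params$rise_time_range) +
      min(params$fall_time_range) + min(params$post_range) >= dur)
    stop_parameter("infeasible timing: rise + fall (plus baselines) exceed the MVC duration")
  with_opt_seed(seed, {
    amp_mean <- params$grade_amplitude_mean[grade] * params$amplitude_scale
    p <- rnorm(1, amp_mean, params$grade_amplitude_sd_frac * amp_mean)
    p <- max(p, 0.3 * amp_mean)
    rt <- params$rise_time_range
    split <- rt[1] + params$rapid_split * diff(rt)
    rapid <- runif(1) < params$strategy_mix
    rise <- if (rapid) runif(1, rt[1], split) else runif(1, split, rt[2])
    fall <- runif(1, params$fall_time_range[1], params$fall_time_range[2])
    pre  <- runif(1, params$pre_range[1], params$pre_range[2])
    post <- runif(1, params$post_range[1], params$post_range[2])
    # keep at least 0.5 s of plateau: shrink the baselines proportionally
    # when a short duration cannot accommodate the drawn pre/post windows
    avail <- dur - rise - fall - 0.5
    if (avail <= 0.4) stop_parameter("infeasible timing for the drawn rise/fall/plateau")
    if (pre + post > avail) {
      sc <- avail / (pre + post)
      pre <- pre * sc; post <- post * sc
    }
    snap <- function(t) round(t * fs) / fs
    tB <- snap(pre); tC <- snap(pre + rise); tE <- snap(dur - post); tD <- snap(tE - fall)
    if (!(tB < tC && tC < tD && tD < tE))
      stop_parameter("infeasible timing for the drawn rise/fall/plateau")
    r  <- runif(1, params$relaxation_residual_range[1], params$relaxation_residual_range[2]) * p
    c0 <- runif(1, params$baseline_offset_range[1], params$baseline_offset_range[2])

    n <- round(dur * fs)
    tt <- (seq_len(n) - 1L) / fs
    clean <- numeric(n)
    clean[tt <= tB] <- 0
    i <- tt > tB & tt <= tC; clean[i] <- p * (tt[i] - tB) / (tC - tB)
    i <- tt > tC & tt <= tD; clean[i] <- p
    i <- tt > tD & tt <= tE; clean[i] <- p + (r - p) * (tt[i] - tD) / (tE - tD)
    clean[tt > tE] <- r
    if (params$ripple_frac > 0) {
      i <- tt > tC & tt <= tD
      clean[i] <- clean[i] + params$ripple_frac * p * sin(2 * pi * 0.5 * (tt[i] - tC))
    }
    sigma <- params$noise_sd * p * params$noise_scale
    noisy <- c0 + clean + rnorm(n, 0, sigma)

    idx <- function(t) as.integer(round(t * fs)) + 1L
    iB <- idx(tB); iC <- idx(tC); iD <- idx(tD); iE <- idx(tE)
    xe <- clean[iB:iE]
    truth_features <- list(
      rising_slope = p / (tC - tB),
      falling_slope = (r - p) / (tE - tD),
      auc = sum(xe[-length(xe)] + xe[-1L]) / (2 * fs),
      f_max = max(clean),
      f_avg = mean(xe),
      t_c = tE - tB,
      relaxation = r,
      f_ab = c0
    )
    list(
      recording = recording(noisy, fs = fs, task = "mvc", mos = grade),
      truth = list(tB = tB, tC = tC, tD = tD, tE = tE,
                   idx_B = iB, idx_C = iC, idx_D = iD, idx_E = iE,
                   plateau = p, residual = r, offset = c0, noise_sd = sigma,
                   rapid = rapid, features = truth_features)
    )
  })
}

#' Generate a synthetic rest recording
#'
#' Baseline offset plus sensor noise only: no PFM movement.
#'
#' @inheritParams gen_mvc
#' @return A [recording()] with task `"rest"`.
#' @export
gen_rest <- function(params = generator_params(), seed = NULL) {
  with_opt_seed(seed, {
    n <- round(params$rest_duration * params$fs)
    c0 <- runif(1, params$baseline_offset_range[1], params$baseline_offset_range[2])
    recording(c0 + rnorm(n, 0, params$sensor_noise_n * params$noise_scale),
              fs = params$fs, task = "rest")
  })
}

#' Generate a synthetic cough recording
#'
#' One to three short high-amplitude half-sine bursts over a noisy baseline;
#' no plateau structure. Spike centres are spread over the trace; a parameter
#' error is raised if the drawn widths cannot fit without overlap.
#'
#' @param n_spikes number of cough spikes (1--3).
#' @inheritParams gen_mvc
#' @return A [recording()] with task `"cough"`.
#' @export
gen_cough <- function(n_spikes = 3L, params = generator_params(), seed = NULL) {
  if (!is_count(n_spikes) || n_spikes < 1 || n_spikes > 3)
    stop_parameter("n_spikes must be 1, 2 or 3")
  with_opt_seed(seed, {
    fs <- params$fs
    dur <- 1.5 * n_spikes + 0.5
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1L) / fs
    widths <- runif(n_spikes, params$cough_width_range[1], params$cough_width_range[2])
    centers <- (seq_len(n_spikes) - 0.5) * dur / n_spikes +
      runif(n_spikes, -0.15, 0.15)
    if (n_spikes > 1L) {
      gaps <- diff(centers) - (widths[-n_spikes] + widths[-1L]) / 2
      if (any(gaps <= 0)) stop_parameter("cough spikes overlap for the drawn widths")
    }
    c0 <- runif(1, params$baseline_offset_range[1], params$baseline_offset_range[2])
    x <- rep(c0, n)
    for (s in seq_len(n_spikes)) {
      amp <- runif(1, params$cough_amp_range[1], params$cough_amp_range[2]) *
        params$amplitude_scale
      lo <- centers[s] - widths[s] / 2; hi <- centers[s] + widths[s] / 2
      i <- tt >= lo & tt <= hi
      x[i] <- x[i] + amp * sin(pi * (tt[i] - lo) / widths[s])
    }
    recording(x + rnorm(n, 0, params$sensor_noise_n * params$noise_scale),
              fs = fs, task = "cough")
  })
}

#' Generate a synthetic push recording
#'
#' Slow low-amplitude linear drift plus sensor noise: bearing-down effort with
#' no sharp rise and no sustained plateau.
#'
#' @inheritParams gen_mvc
#' @return A [recording()] with task `"push"`.
#' @export
gen_push <- function(params = generator_params(), seed = NULL) {
  with_opt_seed(seed, {
    fs <- params$fs
    n <- round(params$push_duration * fs)
    tt <- (seq_len(n) - 1L) / fs
    c0 <- runif(1, params$baseline_offset_range[1], params$baseline_offset_range[2])
    drift <- runif(1, params$push_drift_range[1], params$push_drift_range[2]) *
      params$amplitude_scale
    recording(c0 + drift * tt + rnorm(n, 0, params$sensor_noise_n * params$noise_scale),
              fs = fs, task = "push")
  })
}

#' Generate a labeled set of recordings in memory
#'
#' @param n_per_class named vector/list with counts for `mvc`, `rest`,
#'   `cough`, `push` (missing classes default to 0). `mvc` may be a single
#'   count (grades 1..5 assigned round-robin) or a length-5 vector of counts
#'   per grade.
#' @param params a [generator_params()].
#' @param seed integer seed; every recording derives its own child seed, so
#'   the set is reproducible element-wise.
#' @return A list of items; each has `recording`, and MVC items also `truth`.
#' @export
gen_recordings <- function(n_per_class, params = generator_params(), seed = 1L) {
  nmvc <- n_per_class[["mvc"]] %||% 0
  grades <- if (length(nmvc) == 5L) rep(1:5, times = nmvc)
            else rep(1:5, length.out = nmvc)
  items <- list(); k <- 0L
  for (g in grades) {
    k <- k + 1L
    items[[length(items) + 1L]] <- gen_mvc(g, params, seed = child_seed(seed, k))
  }
  for (i in seq_len(n_per_class[["rest"]] %||% 0)) {
    k <- k + 1L
    items[[length(items) + 1L]] <- list(recording = gen_rest(params, seed = child_seed(seed, k)))
  }
  for (i in seq_len(n_per_class[["cough"]] %||% 0)) {
    k <- k + 1L
    ns <- 1L + (i - 1L) %% 3L
    items[[length(items) + 1L]] <- list(recording = gen_cough(ns, params, seed = child_seed(seed, k)))
  }
  for (i in seq_len(n_per_class[["push"]] %||% 0)) {
    k <- k + 1L
    items[[length(items) + 1L]] <- list(recording = gen_push(params, seed = child_seed(seed, k)))
  }
  items
}

#' Generate a dataset on disk with a manifest
#'
#' Writes one CSV per recording, a ground-truth JSON sidecar per MVC, and a
#' manifest JSON listing every file with its metadata, the seed and the
#' generator parameters. Two runs with the same seed produce byte-identical
#' files.
#'
#' @inheritParams gen_recordings
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly; attribute `"items"` carries the
#'   generated items.
#' @export
gen_dataset <- function(n_per_class, params = generator_params(), dir, seed = 1L) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L) stop_io(sprintf("cannot write to directory: %s", dir))
  items <- gen_recordings(n_per_class, params, seed)
  entries <- vector("list", length(items))
  for (i in seq_along(items)) {
    rec <- items[[i]]$recording
    fname <- sprintf("rec_%04d.csv", i)
    write_recording(rec, file.path(dir, fname))
    if (!is.null(items[[i]]$truth)) {
      jsonlite::write_json(items[[i]]$truth, file.path(dir, sprintf("rec_%04d.truth.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
    entries[[i]] <- list(path = fname, task = rec$task, subject_id = rec$subject_id,
                         session = rec$session, mos = rec$mos,
                         buttock_movement = rec$buttock_movement)
  }
  man <- file.path(dir, "manifest.json")
  write_manifest(entries, man, seed = seed,
                 generator_params = unclass(params))
  attr(man, "items") <- items
  invisible(man)
}
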