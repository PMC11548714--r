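#' Construct a dynamometric force recording
#'
#' A `pfm_recording` holds one force-versus-time trace from an intra-vaginal
#' dynamometer together with its task label and metadata. Force is in newtons,
#' the sampling rate in hertz. Tasks follow the dynamometric protocol: `rest`
#' (quiet baseline), `mvc` (10 s maximal voluntary contraction), `cough`
#' (one to three short expulsive spikes) and `push` (bearing-down effort with
#' no contraction structure).
#'
#' @param samples numeric vector of force values (N); non-empty, all finite.
#' @param fs sampling rate in Hz, > 0.
#' @param task one of `"rest"`, `"mvc"`, `"cough"`, `"push"`.
#' @param subject_id,session opaque identifier strings.
#' @param mos optional Modified Oxford Scale grade, integer 0--5.
#' @param buttock_movement optional logical; `TRUE` when the physiotherapist
#'   observed buttock movement during the task.
#' @return An object of class `pfm_recording`.
#' @export
#' @examples
#' rec <- recording(rnorm(100, 1, 0.02), fs = 20, task = "rest")
#' rec
recording <- function(samples, fs, task = c("rest", "mvc", "cough", "push"),
                      subject_id = "anon", session = "s1",
                      mos = NULL, buttock_movement = NULL) {
  task <- match.arg(task)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_validation("samples must be non-empty")
  if (!all(is.finite(samples))) stop_validation("all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_validation("fs must be a single positive number")
  if (!is.null(mos)) {
    if (!is_count(mos) || mos < 0 || mos > 5)
      stop_validation("mos must be an integer in 0..5")
    mos <- as.integer(mos)
  }
  if (!is.null(buttock_movement)) {
    if (!is.logical(buttock_movement) || length(buttock_movement) != 1L || is.na(buttock_movement))
      stop_validation("buttock_movement must be TRUE or FALSE")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), task = task,
         subject_id = as.character(subject_id), session = as.character(session),
         mos = mos, buttock_movement = buttock_movement),
    class = "pfm_recording"
  )
}

#' @export
print.pfm_recording <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<pfm_recording> task=%s  %d samples @ %g Hz (%.2f s)  subject=%s session=%s\n",
              x$task, length(x$samples), x$fs, dur, x$subject_id, x$session))
  if (!is.null(x$mos)) cat(sprintf("  MOS grade: %d\n", x$mos))
  if (isTRUE(x$buttock_movement)) cat("  buttock movement annotated\n")
  invisible(x)
}

#' Read a recording from a two-column CSV file
#'
#' The file must have a header `time_s,force_n` and strictly increasing,
#' uniformly spaced times. The sampling rate is inferred from the median time
#' step; spacing must be uniform within 1% of that step. The time column is
#' authoritative for `fs`, the force column for values.
#'
#' @param path path to the CSV file.
#' @param task,subject_id,session,mos,buttock_movement metadata for the
#'   returned recording (typically supplied by a manifest).
#' @return A [recording()].
#' @export
read_recording <- function(path, task = "rest", subject_id = "anon", session = "s1",
                           mos = NULL, buttock_movement = NULL) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- tryCatch(
    read.csv(path, header = TRUE, colClasses = "numeric"),
    error = function(e) stop_parse(sprintf("cannot parse %s: %s", path, conditionMessage(e))),
    warning = function(w) stop_parse(sprintf("cannot parse %s: %s", path, conditionMessage(w)))
  )
  if (!all(c("time_s", "force_n") %in% names(df)))
    stop_format(sprintf("%s: expected columns time_s,force_n", path))
  if (nrow(df) == 0L) stop_format(sprintf("%s: empty file", path))
  if (nrow(df) < 2L) stop_format(sprintf("%s: cannot infer sampling rate from one row", path))
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$force_n)))
    stop_parse(sprintf("%s: non-numeric or non-finite cell", path))
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop_format(sprintf("%s: times must be strictly increasing", path))
  step <- median(dt)
  if (any(abs(dt - step) > 0.01 * step))
    stop_format(sprintf("%s: non-uniform time steps beyond 1%% tolerance", path))
  recording(df$force_n, fs = 1 / step, task = task, subject_id = subject_id,
            session = session, mos = mos, buttock_movement = buttock_movement)
}

#' Write a recording to a two-column CSV file
#'
#' Times are reconstructed as `index / fs` starting at 0 and printed with nine
#' decimals (forces with six), so a write/read round trip is lossless to the
#' printed precision and the sampling rate survives inference even at 1024 Hz.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pfm_recording"))
  n <- length(rec$samples)
  t <- (seq_len(n) - 1L) / rec$fs
  lines <- c("time_s,force_n",
             sprintf("%.9f,%.6f", t, rec$samples))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write %s", path))
  invisible(path)
}

#' Load a dataset of recordings from a JSON manifest
#'
#' The manifest is a JSON document
#' `{"entries": [{"path": ..., "task": ..., "subject_id": ..., "session": ...,
#' "mos": ..., "buttock_movement": ...}, ...], "seed": ..., "generator_params": ...}`.
#' Relative paths are resolved against the manifest's directory. Entries are
#' loaded and validated in manifest order.
#'
#' @param manifest_path path to the manifest JSON.
#' @return A list of [recording()] objects, in manifest order.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop_io(sprintf("manifest not found: %s", manifest_path))
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  if (is.null(man$entries) || length(man$entries) == 0L)
    stop_format("manifest has no entries")
  base <- dirname(manifest_path)
  paths <- vapply(man$entries, function(e) e$path, character(1))
  if (anyDuplicated(paths)) stop_validation("manifest paths must be unique")
  lapply(man$entries, function(e) {
    p <- if (grepl("^(/|[A-Za-z]:)", e$path)) e$path else file.path(base, e$path)
    if (!file.exists(p)) stop_io(sprintf("manifest entry missing on disk: %s", e$path))
    read_recording(p,
                   task = e$task %||% "rest",
                   subject_id = e$subject_id %||% "anon",
                   session = e$session %||% "s1",
                   mos = e$mos,
                   buttock_movement = e$buttock_movement)
  })
}

#' Write a dataset manifest
#'
#' @param entries list of entry lists (`path`, `task`, `subject_id`, `session`,
#'   optional `mos`, `buttock_movement`).
#' @param path output path for the JSON manifest.
#' @param seed optional integer recorded for provenance.
#' @param generator_params optional list of generator parameters recorded for
#'   provenance.
#' @return The path, invisibly.
#' @export
write_manifest <- function(entries, path, seed = NULL, generator_params = NULL) {
  man <- list(entries = entries)
  if (!is.null(seed)) man$seed <- seed
  if (!is.null(generator_params)) man$generator_params <- generator_params
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
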