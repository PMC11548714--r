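# Internal helpers shared across modules.

# Consistent condition classes so callers/tests can distinguish failure modes.
pfmqa_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pfmqa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_parameter <- function(msg) pfmqa_stop(msg, "pfmqa_parameter_error")
stop_format    <- function(msg) pfmqa_stop(msg, "pfmqa_format_error")
stop_parse     <- function(msg) pfmqa_stop(msg, "pfmqa_parse_error")
stop_detection <- function(msg) pfmqa_stop(msg, "pfmqa_detection_error")
stop_fit       <- function(msg) pfmqa_stop(msg, "pfmqa_fit_error")
stop_io        <- function(msg) pfmqa_stop(msg, "pfmqa_io_error")
stop_validation<- function(msg) pfmqa_stop(msg, "pfmqa_validation_error")

# Centered moving average, length preserved, edges padded with edge values.
# Width must be odd; width 1 is the identity.
smooth_ma <- function(x, width = 5L) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L)
    stop_parameter("smoothing width must be a positive odd integer")
  if (width == 1L) return(x)
  h <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[(h + 1L):(h + length(x))]
}

# Derive a child seed from a base seed; kept below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
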