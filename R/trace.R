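#' Uniformly sampled voltage trace
#'
#' The common container for every analogue and conditioned signal in the
#' package: a start time, a constant sample interval and a vector of voltages.
#' Sample `k` (0-based) lies at `start_time + k * sample_interval`.
#'
#' @param values Numeric vector of voltages.
#' @param sample_interval Sample spacing, ms.
#' @param start_time Time of the first sample, ms.
#' @param channel_label Free-text channel name.
#' @return An object of class `waveform_trace`.
#' @export
waveform_trace <- function(values, sample_interval, start_time = 0,
                           channel_label = "") {
  stopifnot_scalar(sample_interval, "sample_interval", positive = TRUE)
  stopifnot_scalar(start_time, "start_time")
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  structure(list(
    start_time = start_time,
    sample_interval = sample_interval,
    values = as.numeric(values),
    channel_label = as.character(channel_label)[1]
  ), class = "waveform_trace")
}

#' Sample times of a trace
#'
#' @param trace A [waveform_trace()].
#' @return Numeric vector of sample times, ms.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1) * trace$sample_interval
}

#' Duration and end time of a trace
#'
#' `trace_end()` is the time of the last sample; `trace_duration()` the span
#' from first to last sample.
#'
#' @param trace A [waveform_trace()].
#' @return A length-1 numeric, ms.
#' @export
trace_end <- function(trace) {
  trace$start_time + (length(trace$values) - 1) * trace$sample_interval
}

#' @rdname trace_end
#' @export
trace_duration <- function(trace) {
  (length(trace$values) - 1) * trace$sample_interval
}

#' @export
print.waveform_trace <- function(x, ...) {
  cat(sprintf(
    "<waveform_trace> %s: %d samples @ %g ms (%.1f-%.1f ms), range [%.4g, %.4g] V\n",
    if (nzchar(x$channel_label)) x$channel_label else "(unlabelled)",
    length(x$values), x$sample_interval, x$start_time, trace_end(x),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
as.data.frame.waveform_trace <- function(x, ...) {
  data.frame(time_ms = trace_times(x), volts = x$values)
}

#' @export
plot.waveform_trace <- function(x, ...) {
  plot(trace_times(x), x$values, type = "l",
       xlab = "time (ms)", ylab = "volts",
       main = x$channel_label, ...)
  invisible(x)
}

#' Decimate a trace to a coarser sampling grid
#'
#' Emulates digitisation of a fast master trace at a slower rate by keeping
#' every n-th sample (no interpolation, no anti-alias filtering: the gate
#' microprocessors simply read the instantaneous voltage on their own clock).
#' The target interval must be an integer multiple of the source interval.
#'
#' @param trace A [waveform_trace()].
#' @param sample_interval Target sample interval, ms.
#' @return A decimated [waveform_trace()].
#' @export
resample_trace <- function(trace, sample_interval) {
  stopifnot_scalar(sample_interval, "sample_interval", positive = TRUE)
  step <- sample_interval / trace$sample_interval
  if (abs(step - round(step)) > 1e-9) {
    stop("target sample_interval must be an integer multiple of the trace's",
         call. = FALSE)
  }
  step <- as.integer(round(step))
  if (step == 1L) return(trace)
  idx <- seq(1L, length(trace$values), by = step)
  waveform_trace(trace$values[idx], sample_interval,
                 start_time = trace$start_time,
                 channel_label = trace$channel_label)
}

#' Write / read a trace as CSV
#'
#' Plain-text interchange format: header `time_ms,volts`, one sample per row,
#' values printed at full double precision so that a write/read round trip is
#' lossless.
#'
#' @param trace A [waveform_trace()].
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a [waveform_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms,volts", con)
  writeLines(sprintf("%.17g,%.17g", trace_times(trace), trace$values), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param channel_label Channel label to attach on read.
#' @export
read_trace_csv <- function(path, channel_label = "") {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("time_ms", "volts") %in% names(df)) || nrow(df) < 1L) {
    stop("not a trace CSV (need columns time_ms, volts)", call. = FALSE)
  }
  if (nrow(df) > 1L) {
    dt <- diff(df$time_ms)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
      stop("trace CSV is not uniformly sampled", call. = FALSE)
    }
    interval <- (df$time_ms[nrow(df)] - df$time_ms[1]) / (nrow(df) - 1)
  } else {
    interval <- 1
  }
  waveform_trace(df$volts, interval, start_time = df$time_ms[1],
                 channel_label = channel_label)
}
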