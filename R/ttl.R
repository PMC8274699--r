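#' Binary TTL control signal
#'
#' Scanner-facing gate lines are represented by their high intervals: an
#' ordered, non-overlapping set of `[start, end)` intervals in ms, a polarity
#' declaring whether the high level means "acquire" (some scanners use 0 V as
#' the instruction-to-image, others 5 V), and the observation window over
#' which the signal is defined (needed to complement the signal when the
#' polarity is flipped).
#'
#' @param high_intervals Two-column numeric matrix (or data.frame) of interval
#'   starts and ends, ms; may have zero rows.
#' @param polarity `"high_means_acquire"` or `"low_means_acquire"`.
#' @param label Free-text signal name.
#' @param window Length-2 numeric, the monitored time window `[start, end]`.
#' @return An object of class `ttl_signal`.
#' @export
ttl_signal <- function(high_intervals, polarity = "high_means_acquire",
                       label = "", window = NULL) {
  if (is.data.frame(high_intervals)) high_intervals <- as.matrix(high_intervals)
  if (is.null(high_intervals) || length(high_intervals) == 0L) {
    high_intervals <- matrix(numeric(0), ncol = 2)
  }
  if (!is.matrix(high_intervals) || ncol(high_intervals) != 2) {
    stop("high_intervals must be a 2-column matrix of (start, end)", call. = FALSE)
  }
  storage.mode(high_intervals) <- "double"
  colnames(high_intervals) <- c("start", "end")
  n <- nrow(high_intervals)
  if (n > 0) {
    if (any(high_intervals[, 2] <= high_intervals[, 1])) {
      stop("every TTL interval must have end > start", call. = FALSE)
    }
    if (n > 1 && any(high_intervals[-1, 1] < high_intervals[-n, 2])) {
      stop("TTL intervals must be non-overlapping and strictly increasing", call. = FALSE)
    }
  }
  polarity <- match.arg(polarity, c("high_means_acquire", "low_means_acquire"))
  if (is.null(window)) {
    window <- if (n > 0) c(high_intervals[1, 1], high_intervals[n, 2]) else c(0, 0)
  }
  if (length(window) != 2 || window[2] < window[1]) {
    stop("window must be c(start, end) with end >= start", call. = FALSE)
  }
  structure(list(
    high_intervals = high_intervals,
    polarity = polarity,
    label = as.character(label)[1],
    window = as.numeric(window)
  ), class = "ttl_signal")
}

#' @export
print.ttl_signal <- function(x, ...) {
  cat(sprintf(
    "<ttl_signal> %s: %d high interval(s), polarity %s, window [%.1f, %.1f] ms\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    nrow(x$high_intervals), x$polarity, x$window[1], x$window[2]
  ))
  invisible(x)
}

#' Query the TTL level at given times
#'
#' @param ttl A [ttl_signal()].
#' @param times Numeric vector of times, ms.
#' @return Logical vector: is the line high at each time? Intervals are
#'   half-open `[start, end)`.
#' @export
ttl_is_high <- function(ttl, times) {
  iv <- ttl$high_intervals
  if (nrow(iv) == 0) return(rep(FALSE, length(times)))
  idx <- findInterval(times, iv[, 1])
  idx > 0 & times < iv[pmax(idx, 1L), 2]
}

#' Flip TTL polarity
#'
#' Returns the complement of the high intervals within the signal's window
#' and toggles the polarity flag, so the acquire/no-acquire meaning is
#' preserved (this mirrors the polarity switch on the gating hardware).
#'
#' @param ttl A [ttl_signal()].
#' @return A [ttl_signal()] with opposite polarity.
#' @export
flip_polarity <- function(ttl) {
  iv <- ttl$high_intervals
  w <- ttl$window
  edges <- c(w[1], t(iv[, , drop = FALSE]), w[2])
  comp <- matrix(edges, ncol = 2, byrow = TRUE)
  comp <- comp[comp[, 2] > comp[, 1], , drop = FALSE]
  ttl_signal(comp,
             polarity = setdiff(c("high_means_acquire", "low_means_acquire"),
                                ttl$polarity),
             label = ttl$label, window = w)
}

#' Normalise a TTL signal to high-means-acquire polarity
#'
#' @param ttl A [ttl_signal()].
#' @return The same signal expressed with `"high_means_acquire"` polarity.
#' @export
as_acquire_high <- function(ttl) {
  if (ttl$polarity == "high_means_acquire") ttl else flip_polarity(ttl)
}

# Intersection of two ordered interval sets (2-column matrices).
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), ncol = 2))
  out <- matrix(numeric(0), ncol = 2)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1])
    hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) out <- rbind(out, c(lo, hi))
    if (a[i, 2] <= b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  out
}

#' Boolean AND of the cardiac and respiratory gates
#'
#' The combined cardio-respiratory control signal is high exactly where both
#' inputs are high; a cardiac TTL pulse that straddles the edge of an acquire
#' window is truncated at the edge. Both inputs must already be expressed in
#' high-means-acquire polarity (use [as_acquire_high()] first).
#'
#' @param ecg_ttl Cardiac gate, a [ttl_signal()].
#' @param acquire_ttl Respiratory acquire window signal, a [ttl_signal()].
#' @return A [ttl_signal()] labelled `"cr_ttl"`.
#' @export
combine_gates <- function(ecg_ttl, acquire_ttl) {
  if (ecg_ttl$polarity != "high_means_acquire" ||
      acquire_ttl$polarity != "high_means_acquire") {
    stop("both gates must be in high_means_acquire polarity; see as_acquire_high()",
         call. = FALSE)
  }
  iv <- intersect_intervals(ecg_ttl$high_intervals, acquire_ttl$high_intervals)
  window <- c(min(ecg_ttl$window[1], acquire_ttl$window[1]),
              max(ecg_ttl$window[2], acquire_ttl$window[2]))
  ttl_signal(iv, polarity = "high_means_acquire", label = "cr_ttl",
             window = window)
}

#' Render a TTL signal as a sampled 0/5 V trace
#'
#' For plotting alongside the analogue traces in the style of the gate
#' hardware's nine-channel display.
#'
#' @param ttl A [ttl_signal()].
#' @param sample_interval Sampling interval, ms.
#' @param high_level Voltage of the high level.
#' @return A [waveform_trace()].
#' @export
ttl_to_trace <- function(ttl, sample_interval = 1, high_level = 5) {
  times <- seq(ttl$window[1], ttl$window[2], by = sample_interval)
  waveform_trace(ifelse(ttl_is_high(ttl, times), high_level, 0),
                 sample_interval, start_time = ttl$window[1],
                 channel_label = ttl$label)
}

#' Write / read a TTL signal as JSON
#'
#' The file holds the label, polarity, window and a list of
#' `{start_ms, end_ms, label}` interval records; a round trip reproduces the
#' signal exactly.
#'
#' @param ttl A [ttl_signal()].
#' @param path File path.
#' @return `write_ttl_json()` returns `path` invisibly; `read_ttl_json()`
#'   returns a [ttl_signal()].
#' @export
write_ttl_json <- function(ttl, path) {
  iv <- ttl$high_intervals
  obj <- list(
    label = ttl$label,
    polarity = ttl$polarity,
    window_ms = ttl$window,
    high_intervals = if (nrow(iv) > 0) {
      data.frame(start_ms = iv[, 1], end_ms = iv[, 2], label = ttl$label)
    } else {
      data.frame(start_ms = numeric(0), end_ms = numeric(0),
                 label = character(0))
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ttl_json
#' @export
read_ttl_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- obj$high_intervals
  m <- if (length(iv) > 0 && nrow(iv) > 0) {
    cbind(iv$start_ms, iv$end_ms)
  } else {
    matrix(numeric(0), ncol = 2)
  }
  ttl_signal(m, polarity = obj$polarity, label = obj$label,
             window = as.numeric(obj$window_ms))
}
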