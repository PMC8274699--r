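# Default (linear) phase-encode acquisition ordering.
encode_order <- function(params) {
  0:(params$n_phase_encodes - 1)
}

#' Centre-out phase-encode ordering for localiser scans
#'
#' Orders phase-encode indices by distance from the centre line `n/2`
#' (ties: lower index first), as used by the segmented localiser mode that
#' acquires a few lines per R-wave starting at the centre of k-space.
#'
#' @param n Number of phase encodes.
#' @return Integer vector of 0-based indices in acquisition order.
#' @export
centre_out_order <- function(n) {
  idx <- 0:(n - 1)
  idx[order(abs(idx - n / 2), idx)]
}

new_schedule <- function(blocks, breath_declarations, rf_pulse_times, params,
                         window, complete) {
  total <- if (nrow(blocks) > 0) {
    max(blocks$start_time) + params$n_frames * params$tr - window[1]
  } else {
    0
  }
  structure(list(
    blocks = blocks,
    breath_declarations = breath_declarations,
    rf_pulse_times = rf_pulse_times,
    params = params,
    window = window,
    complete = complete,
    total_duration = total
  ), class = "acquisition_schedule")
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf(
    "<acquisition_schedule> mode %s: %d block(s) (%d kept, %d re-acquired), %d breath declaration(s), %.1f s%s\n",
    x$params$mode, nrow(x$blocks), sum(x$blocks$status == "kept"),
    sum(x$blocks$status == "discarded_reacquired"),
    length(x$breath_declarations), x$total_duration / 1000,
    if (x$complete) "" else " [INCOMPLETE]"
  ))
  invisible(x)
}

#' Frame times of one CINE block
#'
#' Frames lie at `start_time + (0:(n_frames-1)) * tr`.
#'
#' @param schedule An `acquisition_schedule`.
#' @param block Block row index (1-based).
#' @return Numeric vector of frame times, ms.
#' @export
block_frame_times <- function(schedule, block) {
  b <- schedule$blocks[block, ]
  b$start_time + (0:(schedule$params$n_frames - 1)) * schedule$params$tr
}

#' Run the steady-state-maintained gated CINE scan
#'
#' Discrete-time state machine of the constant-TR pulse sequence. The scanner
#' clock ticks every TR from the start of the gating window; RF is applied on
#' every tick (steady-state maintenance). A tick in gate-evaluation mode
#' reads the combined cardio-respiratory TTL level at tick start: a high
#' level launches an `n_frames`-frame CINE block for the next pending phase
#' encode (frames on consecutive ticks), after which gate evaluation
#' resumes. When the count of consecutive gate-evaluation ticks exceeds
#' `breath_count_threshold`, a breath (or missed R-wave) is declared: the
#' `n_reacquire` most recently acquired blocks are marked
#' `discarded_reacquired` and their phase encodes re-queued ahead of the
#' remaining lines, to be re-acquired once triggers resume after the same
#' breath. The scan ends when every phase encode has exactly one kept block.
#'
#' Because the gate is only read on the TR grid, a trigger arriving with
#' uniform phase relative to the clock starts its first frame after a delay
#' uniform on (0, TR] - mean TR/2 (see [trigger_jitter_stats()]).
#'
#' @param cr_ttl Combined cardio-respiratory gate, a [ttl_signal()] in
#'   high-means-acquire polarity. Pulses shorter than one TR can be missed by
#'   tick sampling and raise a warning.
#' @param params A [scan_params()].
#' @param order Optional phase-encode acquisition order (0-based); default
#'   linear.
#' @param max_duration Give up after this much scan time, ms; default: the
#'   TTL window plus one breath-declaration latency.
#' @return An object of class `acquisition_schedule`: `blocks` (data frame
#'   with `phase_encode_index`, `trigger_time`, `start_time`, `status`),
#'   `breath_declarations`, `rf_pulse_times`, `total_duration`, `complete`.
#' @export
run_scan <- function(cr_ttl, params = scan_params(), order = NULL,
                     max_duration = NULL) {
  stopifnot(inherits(cr_ttl, "ttl_signal"), inherits(params, "scan_params"))
  if (cr_ttl$polarity != "high_means_acquire") {
    stop("cr_ttl must be in high_means_acquire polarity", call. = FALSE)
  }
  iv <- cr_ttl$high_intervals
  if (nrow(iv) > 0 && any(iv[, 2] - iv[, 1] < params$tr)) {
    warning("TTL pulse(s) shorter than one TR may be missed by tick sampling",
            call. = FALSE)
  }
  tr <- params$tr
  ne <- params$n_frames
  t0 <- cr_ttl$window[1]
  if (is.null(max_duration)) {
    max_duration <- (cr_ttl$window[2] - t0) +
      (params$breath_count_threshold + 2) * tr
  }
  t_max <- t0 + max_duration
  queue <- if (is.null(order)) encode_order(params) else as.integer(order)

  pe <- integer(0); trig <- numeric(0); start <- numeric(0)
  status <- character(0)
  kept_rows <- integer(0)        # row indices of currently kept blocks
  declarations <- numeric(0)
  t <- t0
  w_end <- cr_ttl$window[2]
  gate_count <- 0L
  declared <- FALSE

  # After the last phase encode is kept, gate evaluation continues until the
  # next trigger (confirming no breath followed the final blocks) or the end
  # of the monitored window; a declaration in that tail re-queues blocks as
  # usual, so data acquired just before a trailing breath are still repaired.
  repeat {
    if (t > t_max) break
    if (length(queue) == 0 && t > w_end) break
    if (ttl_is_high(cr_ttl, t)) {
      if (length(queue) == 0) break     # trigger: no breath followed, done
      k <- findInterval(t, iv[, 1])
      onset <- iv[k, 1]
      row <- length(pe) + 1L
      pe[row] <- queue[1]
      queue <- queue[-1]
      trig[row] <- onset
      start[row] <- t
      status[row] <- "kept"
      kept_rows <- c(kept_rows, row)
      t <- t + ne * tr
      gate_count <- 0L
      declared <- FALSE
    } else {
      # batch all consecutive low ticks up to the next possible high tick
      k <- findInterval(t, iv[, 1])
      next_onset <- if (k < nrow(iv)) iv[k + 1L, 1] else Inf
      t_high <- if (is.finite(next_onset)) {
        t + tr * ceiling((next_onset - t) / tr)
      } else {
        t_max + tr
      }
      t_high <- min(t_high, t_max + tr)
      m <- max(1, round((t_high - t) / tr))   # low ticks at t, t+tr, ...
      decl_t <- t + (params$breath_count_threshold - gate_count) * tr
      if (!declared && gate_count + m > params$breath_count_threshold &&
          decl_t <= w_end) {
        declared <- TRUE
        declarations <- c(declarations, decl_t)
        nre <- min(params$n_reacquire, length(kept_rows))
        if (nre > 0) {
          redo <- kept_rows[(length(kept_rows) - nre + 1):length(kept_rows)]
          status[redo] <- "discarded_reacquired"
          queue <- c(pe[redo], queue)
          kept_rows <- kept_rows[seq_len(length(kept_rows) - nre)]
        }
      }
      gate_count <- gate_count + m
      t <- t + m * tr
    }
  }
  complete <- length(queue) == 0
  if (!complete) {
    if (length(pe) == 0) {
      stop("gate never went high: no CINE block could be launched", call. = FALSE)
    }
    warning(sprintf("scan incomplete: %d phase encode(s) not acquired within max_duration",
                    length(queue)), call. = FALSE)
  }
  end_t <- if (complete && length(start) > 0) {
    max(start) + ne * tr
  } else {
    t
  }
  blocks <- data.frame(
    phase_encode_index = pe, trigger_time = trig, start_time = start,
    status = status, stringsAsFactors = FALSE
  )
  rf <- seq(t0, end_t - tr, by = tr)
  new_schedule(blocks, declarations, rf, params, c(t0, end_t), complete)
}

#' Run a conventionally triggered (cCRT) scan
#'
#' Conventional cardio-respiratory triggering: the scanner idles (no RF)
#' until an R-wave arrives inside a respiratory acquire window, runs one CINE
#' block starting at the trigger, then idles again. Breaths suspend scanning
#' entirely; there is no re-acquisition. The RF pulse train therefore runs at
#' a mix of repetition times: TR inside blocks, and the erratic inter-trigger
#' interval between them.
#'
#' @param ecg_ttl Cardiac gate, a [ttl_signal()] (high-means-acquire).
#' @param resp_acquire_ttl Respiratory acquire-window signal
#'   (high-means-acquire).
#' @param params A [scan_params()].
#' @param order Optional phase-encode order (0-based).
#' @return An `acquisition_schedule` whose `rf_pulse_times` contain only the
#'   CINE frames.
#' @export
run_scan_ccrt <- function(ecg_ttl, resp_acquire_ttl, params = scan_params(mode = "ccrt"),
                          order = NULL) {
  stopifnot(inherits(ecg_ttl, "ttl_signal"), inherits(resp_acquire_ttl, "ttl_signal"))
  if (ecg_ttl$polarity != "high_means_acquire" ||
      resp_acquire_ttl$polarity != "high_means_acquire") {
    stop("gates must be in high_means_acquire polarity", call. = FALSE)
  }
  tr <- params$tr
  ne <- params$n_frames
  onsets <- ecg_ttl$high_intervals[, 1]
  queue <- if (is.null(order)) encode_order(params) else as.integer(order)
  pe <- integer(0); trig <- numeric(0); start <- numeric(0)
  t_free <- -Inf
  for (on in onsets) {
    if (length(queue) == 0) break
    if (on < t_free) next
    if (!ttl_is_high(resp_acquire_ttl, on)) next
    row <- length(pe) + 1L
    pe[row] <- queue[1]
    queue <- queue[-1]
    trig[row] <- on
    start[row] <- on
    t_free <- on + ne * tr
  }
  if (length(pe) == 0) {
    stop("no trigger arrived inside an acquire window", call. = FALSE)
  }
  complete <- length(queue) == 0
  if (!complete) {
    warning(sprintf("scan incomplete: %d phase encode(s) not acquired (stream exhausted)",
                    length(queue)), call. = FALSE)
  }
  blocks <- data.frame(
    phase_encode_index = pe, trigger_time = trig, start_time = start,
    status = rep("kept", length(pe)), stringsAsFactors = FALSE
  )
  rf <- as.numeric(t(outer(start, (0:(ne - 1)) * tr, "+")))
  t0 <- min(ecg_ttl$window[1], resp_acquire_ttl$window[1])
  end_t <- max(start) + ne * tr
  new_schedule(blocks, numeric(0), rf, params, c(t0, end_t), complete)
}

#' Run a double-gated (DG) scan
#'
#' Double gating: an RF block runs after every detected R-wave, including
#' those during breaths, which keeps the magnetization exercised at every
#' heartbeat; but between the end of one block and the next trigger there is
#' an RF hiatus of `R-R - n_frames*tr`, so intensities remain modulated by
#' the (erratic) R-R interval. Data are kept only for triggers falling inside
#' a respiratory acquire window (blocks run during breaths are recorded with
#' status `"no_data"`); without a respiratory signal every block carries
#' data.
#'
#' @param ecg_ttl Cardiac gate, a [ttl_signal()] (high-means-acquire).
#' @param params A [scan_params()].
#' @param resp_acquire_ttl Optional respiratory acquire-window signal.
#' @param order Optional phase-encode order (0-based).
#' @return An `acquisition_schedule`.
#' @export
run_scan_dg <- function(ecg_ttl, params = scan_params(mode = "dg"),
                        resp_acquire_ttl = NULL, order = NULL) {
  stopifnot(inherits(ecg_ttl, "ttl_signal"))
  if (ecg_ttl$polarity != "high_means_acquire") {
    stop("ecg_ttl must be in high_means_acquire polarity", call. = FALSE)
  }
  tr <- params$tr
  ne <- params$n_frames
  onsets <- ecg_ttl$high_intervals[, 1]
  queue <- if (is.null(order)) encode_order(params) else as.integer(order)
  pe <- integer(0); trig <- numeric(0); start <- numeric(0)
  status <- character(0)
  t_free <- -Inf
  for (on in onsets) {
    if (length(queue) == 0) break
    if (on < t_free) next   # block overruns the beat: truncated wait, skip
    row <- length(pe) + 1L
    in_acquire <- is.null(resp_acquire_ttl) || ttl_is_high(resp_acquire_ttl, on)
    if (in_acquire) {
      pe[row] <- queue[1]
      queue <- queue[-1]
      status[row] <- "kept"
    } else {
      pe[row] <- NA_integer_
      status[row] <- "no_data"
    }
    trig[row] <- on
    start[row] <- on
    t_free <- on + ne * tr
  }
  if (sum(status == "kept") == 0) {
    stop("no data-carrying block could be launched", call. = FALSE)
  }
  complete <- length(queue) == 0
  if (!complete) {
    warning(sprintf("scan incomplete: %d phase encode(s) not acquired (stream exhausted)",
                    length(queue)), call. = FALSE)
  }
  blocks <- data.frame(
    phase_encode_index = pe, trigger_time = trig, start_time = start,
    status = status, stringsAsFactors = FALSE
  )
  rf <- as.numeric(t(outer(start, (0:(ne - 1)) * tr, "+")))
  end_t <- max(start) + ne * tr
  new_schedule(blocks, numeric(0), rf, params, c(ecg_ttl$window[1], end_t),
               complete)
}

#' Trigger-to-first-frame jitter statistics
#'
#' In the steady-state-maintained mode the gate is evaluated once per TR, so
#' the first CINE frame starts at the first tick after the TTL onset: a delay
#' uniformly distributed over one TR with mean TR/2 when triggers arrive with
#' uniform phase relative to the TR clock.
#'
#' @param schedule An `acquisition_schedule` (or list of them) from
#'   [run_scan()].
#' @param n_bins Bins for the uniformity chi-square test.
#' @return A list: `delays` (ms), `mean_delay` (ms), `mean_delay_tr`
#'   (in TR units), `tr`, and `uniformity_p` (chi-square goodness-of-fit
#'   p-value against a uniform histogram on (0, TR]).
#' @export
trigger_jitter_stats <- function(schedule, n_bins = 10) {
  schedules <- if (inherits(schedule, "acquisition_schedule")) {
    list(schedule)
  } else {
    schedule
  }
  tr <- schedules[[1]]$params$tr
  delays <- unlist(lapply(schedules, function(s) {
    s$blocks$start_time - s$blocks$trigger_time
  }))
  p <- NA_real_
  if (length(delays) >= 5 * n_bins && stats::var(delays) > 0) {
    counts <- table(cut(delays, breaks = seq(0, tr, length.out = n_bins + 1),
                        include.lowest = TRUE))
    p <- stats::chisq.test(as.numeric(counts))$p.value
  }
  list(delays = delays, mean_delay = mean(delays),
       mean_delay_tr = mean(delays) / tr, tr = tr, uniformity_p = p)
}

#' Bookkeeping totals of a completed schedule
#'
#' @param schedule A complete `acquisition_schedule`.
#' @return A list: `total_duration` (ms, last frame end minus scan start),
#'   `kept_blocks`, `reacquired_blocks`, `breaths_declared`.
#' @export
scan_time_summary <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  if (!schedule$complete) {
    kept <- schedule$blocks$phase_encode_index[schedule$blocks$status == "kept"]
    missing <- setdiff(0:(schedule$params$n_phase_encodes - 1), kept)
    stop(sprintf("schedule incomplete: missing phase encode(s) %s",
                 paste(utils::head(missing, 10), collapse = ", ")),
         call. = FALSE)
  }
  list(
    total_duration = schedule$total_duration,
    kept_blocks = sum(schedule$blocks$status == "kept"),
    reacquired_blocks = sum(schedule$blocks$status == "discarded_reacquired"),
    breaths_declared = length(schedule$breath_declarations)
  )
}

#' Export a schedule as JSON lines
#'
#' One JSON object per CINE block, followed by reading support via
#' [read_schedule_jsonl()].
#'
#' @param schedule An `acquisition_schedule`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_schedule_jsonl <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(schedule$blocks))) {
    b <- schedule$blocks[i, ]
    writeLines(jsonlite::toJSON(list(
      phase_encode_index = b$phase_encode_index,
      trigger_time = b$trigger_time,
      frame_times = block_frame_times(schedule, i),
      status = b$status
    ), auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_schedule_jsonl
#' @return `read_schedule_jsonl()` returns a data frame of block records.
#' @export
read_schedule_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    data.frame(
      phase_encode_index = if (is.null(o$phase_encode_index)) NA_integer_ else o$phase_encode_index,
      trigger_time = o$trigger_time,
      start_time = o$frame_times[1],
      status = o$status, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
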