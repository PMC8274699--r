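#' Two-point differential of the respiration signal
#'
#' The respiration gate digitises the scaled signal every `sample_interval`
#' ms (10 ms by default) and differences adjacent samples,
#' `y[k] = x[k] - x[k-1]` (first sample defined as 0). This acts as a high
#' pass filter: baseline drifts with periods much longer than the sampling
#' interval are strongly attenuated, while the breath's fast leading edge
#' survives.
#'
#' @param trace A [waveform_trace()]; resampled to `cfg$sample_interval` if
#'   needed (the trace's interval must divide it).
#' @param cfg A [resp_gate_config()].
#' @return A [waveform_trace()] of the differential on the gate's grid.
#' @export
resp_differential <- function(trace, cfg = resp_gate_config()) {
  stopifnot(inherits(trace, "waveform_trace"), inherits(cfg, "resp_gate_config"))
  x <- resample_trace(trace, cfg$sample_interval)
  if (length(x$values) < 2L) {
    stop("trace too short to difference (need at least 2 samples on the gate grid)",
         call. = FALSE)
  }
  waveform_trace(c(0, diff(x$values)), x$sample_interval,
                 start_time = x$start_time,
                 channel_label = "resp_diff")
}

# Shared threshold/trailing-edge pulse engine.
#
# `monitor` drives onset detection (threshold crossing upward);
# `term_signal` drives termination: the pulse ends when it falls below
# onset_value + trailing_fraction * (running max - onset_value). In
# differential mode both are the differential; in slope mode the monitor is
# the per-ms slope and termination tracks the raw scaled voltage.
detect_pulses <- function(times, monitor, term_signal, cfg) {
  n <- length(times)
  dt <- times[2] - times[1]
  timeout_steps <- max(1L, ceiling(cfg$termination_timeout / dt))
  onset_i <- integer(0); end_i <- integer(0)
  onset_val <- numeric(0); max_val <- numeric(0)
  term_level <- numeric(0); timed_out <- logical(0)
  i <- 1L
  while (i <= n) {
    crossed <- monitor[i] >= cfg$threshold &&
      (i == 1L || monitor[i - 1L] < cfg$threshold)
    if (!crossed) {
      i <- i + 1L
      next
    }
    o <- term_signal[i]
    mx <- o
    lvl <- o
    j <- i + 1L
    ended <- FALSE
    while (j <= n && (j - i) < timeout_steps) {
      if (term_signal[j] > mx) mx <- term_signal[j]
      lvl <- o + cfg$trailing_fraction * (mx - o)
      if (term_signal[j] < lvl) {
        ended <- TRUE
        break
      }
      j <- j + 1L
    }
    j <- min(j, n)
    onset_i <- c(onset_i, i); end_i <- c(end_i, j)
    onset_val <- c(onset_val, o); max_val <- c(max_val, mx)
    term_level <- c(term_level, lvl); timed_out <- c(timed_out, !ended)
    i <- j + 1L
  }
  data.frame(
    onset_time = times[onset_i],
    end_time = times[pmax(end_i, 1L)],
    onset_value = onset_val,
    max_value = max_val,
    termination_level = term_level,
    timed_out = timed_out
  )
}

# Assemble the three gate lines from detected threshold pulses.
build_resp_result <- function(pulses, filtered, window, cfg) {
  thr_iv <- if (nrow(pulses) > 0) {
    cbind(pulses$onset_time,
          pmax(pulses$end_time, pulses$onset_time + 1e-9))
  } else {
    matrix(numeric(0), ncol = 2)
  }
  # no-acquire: threshold pulse extended by the user dial, clamped to window
  na_iv <- thr_iv
  if (nrow(na_iv) > 0) {
    na_iv[, 2] <- pmin(na_iv[, 2] + cfg$no_acquire_extension, window[2])
    # merge overlaps after extension
    merged <- matrix(numeric(0), ncol = 2)
    for (r in seq_len(nrow(na_iv))) {
      if (nrow(merged) > 0 && na_iv[r, 1] <= merged[nrow(merged), 2]) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], na_iv[r, 2])
      } else {
        merged <- rbind(merged, na_iv[r, ])
      }
    }
    na_iv <- merged
  }
  # acquire: complement of no-acquire in the window, optionally shortened;
  # time cut off an acquire window reverts to the no-acquire line so the two
  # always tile the monitored timeline
  edges <- c(window[1], t(na_iv), window[2])
  acq_iv <- matrix(edges, ncol = 2, byrow = TRUE)
  acq_iv <- acq_iv[acq_iv[, 2] > acq_iv[, 1], , drop = FALSE]
  if (is.finite(cfg$acquire_max_duration) && nrow(acq_iv) > 0) {
    cut <- acq_iv[, 2] - acq_iv[, 1] > cfg$acquire_max_duration
    if (any(cut)) {
      extra <- cbind(acq_iv[cut, 1] + cfg$acquire_max_duration, acq_iv[cut, 2])
      acq_iv[cut, 2] <- acq_iv[cut, 1] + cfg$acquire_max_duration
      na_iv <- rbind(na_iv, extra)
      na_iv <- na_iv[order(na_iv[, 1]), , drop = FALSE]
    }
  }
  structure(list(
    threshold_ttl = ttl_signal(thr_iv, label = "dTTL_Threshold", window = window),
    no_acquire_ttl = ttl_signal(na_iv, label = "dTTL_NoAcquire", window = window),
    acquire_ttl = ttl_signal(acq_iv, label = "dTTL_Acquire", window = window),
    filtered_trace = filtered,
    breaths = pulses,
    config = cfg
  ), class = "resp_gate_result")
}

#' @export
print.resp_gate_result <- function(x, ...) {
  cat(sprintf(
    "<resp_gate_result> %d breath(s) detected (%d force-terminated), %d acquire window(s)\n",
    nrow(x$breaths), sum(x$breaths$timed_out), nrow(x$acquire_ttl$high_intervals)
  ))
  invisible(x)
}

#' Detect breaths and generate the respiratory gate lines
#'
#' Implements the respiration gating algorithm on the 10 ms digitisation
#' grid. A threshold pulse (`dTTL_Threshold`) begins when the 2-point
#' differential of the scaled signal crosses `threshold` upward (the first
#' sample at or above the threshold supplies the onset voltage); it ends when
#' the signal falls through the termination level
#' `onset + trailing_fraction * (max - onset)` - terminating on a fraction of
#' the excursion rather than on the onset level guards against breath
#' profiles whose baseline is not reached between breaths. A pulse whose
#' trailing edge never crosses the level is force-terminated after
#' `termination_timeout` ms. Each pulse, extended by `no_acquire_extension`,
#' forms a `dTTL_NoAcquire` window; the gaps in between are the
#' `dTTL_Acquire` windows (optionally shortened to `acquire_max_duration`).
#' An acquire window always ends at the next breath detection. Acquire and
#' no-acquire windows tile the monitored timeline without overlap.
#'
#' @param trace The voltage-scaled respiration [waveform_trace()].
#' @param cfg A [resp_gate_config()].
#' @return An object of class `resp_gate_result` with elements
#'   `threshold_ttl`, `no_acquire_ttl`, `acquire_ttl` ([ttl_signal()]s),
#'   `filtered_trace` (the differential) and `breaths` (a data frame with one
#'   row per detected breath: onset/end times, onset/max values, the
#'   termination level actually used, and a timeout flag).
#' @export
detect_breaths <- function(trace, cfg = resp_gate_config()) {
  stopifnot(inherits(trace, "waveform_trace"), inherits(cfg, "resp_gate_config"))
  if (cfg$mode == "slope") return(slope_trigger(trace, cfg))
  filtered <- resp_differential(trace, cfg)
  times <- trace_times(filtered)
  pulses <- detect_pulses(times, filtered$values, filtered$values, cfg)
  if (any(pulses$timed_out)) {
    message(sprintf("detect_breaths: %d pulse(s) force-terminated after %g ms timeout",
                    sum(pulses$timed_out), cfg$termination_timeout))
  }
  build_resp_result(pulses, filtered, c(times[1], times[length(times)]), cfg)
}

#' Slope-triggered breath detection
#'
#' Alternative trigger for the respiratory gate: the threshold pulse starts
#' when the leading-edge slope of the scaled respiration signal (volts/ms on
#' the gate's grid) exceeds `threshold`, and is terminated when the raw
#' scaled voltage returns through 20% (the `trailing_fraction`) of the
#' voltage excursion between detection and peak.
#'
#' @inheritParams detect_breaths
#' @return A `resp_gate_result`, as [detect_breaths()].
#' @export
slope_trigger <- function(trace, cfg = resp_gate_config(mode = "slope")) {
  stopifnot(inherits(trace, "waveform_trace"), inherits(cfg, "resp_gate_config"))
  x <- resample_trace(trace, cfg$sample_interval)
  filtered <- resp_differential(trace, cfg)
  slope <- filtered$values / cfg$sample_interval   # volts per ms
  times <- trace_times(filtered)
  pulses <- detect_pulses(times, slope, x$values, cfg)
  if (any(pulses$timed_out)) {
    message(sprintf("slope_trigger: %d pulse(s) force-terminated after %g ms timeout",
                    sum(pulses$timed_out), cfg$termination_timeout))
  }
  build_resp_result(pulses, filtered, c(times[1], times[length(times)]), cfg)
}
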