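#' Two-point ECG difference over a fixed lag
#'
#' The cardiac gate digitises the scaled ECG at the base rate (1 kHz) and
#' computes `y[k] = x[k] - x[k - diff_lag/base_sample_interval]`, a high-pass
#' filter that removes the slow respiration-induced voltage while keeping the
#' R-wave's fast rising edge as a large step. The lag (4 ms by default)
#' equals one TR, so gradient pickup that repeats every TR cancels in the
#' difference. The first `diff_lag` worth of samples is defined as 0.
#'
#' @param trace The voltage-scaled ECG [waveform_trace()]; decimated to the
#'   base rate internally.
#' @param cfg An [ecg_gate_config()].
#' @return A [waveform_trace()] of the difference signal on the base grid.
#' @export
ecg_difference <- function(trace, cfg = ecg_gate_config()) {
  stopifnot(inherits(trace, "waveform_trace"), inherits(cfg, "ecg_gate_config"))
  x <- resample_trace(trace, cfg$base_sample_interval)
  lag <- as.integer(round(cfg$diff_lag / cfg$base_sample_interval))
  if (length(x$values) <= lag) {
    stop("trace shorter than the difference lag", call. = FALSE)
  }
  v <- x$values
  d <- c(rep(0, lag), v[(lag + 1):length(v)] - v[seq_len(length(v) - lag)])
  waveform_trace(d, x$sample_interval, start_time = x$start_time,
                 channel_label = "ecg_diff")
}

#' Detect R-waves with the two-rate turning-point algorithm
#'
#' State machine of the cardiac gate. IDLE: the difference signal
#' ([ecg_difference()]) is evaluated at every base sample; when it exceeds
#' `arm_threshold` (and the detector is outside its refractory period) the
#' gate ARMS. ARMED: the raw voltage-scaled ECG is sampled at the fast rate
#' (10 kHz); the first fast sample lower than its predecessor marks the
#' turning point, the R-wave peak being the predecessor (a flat top resolves
#' to the first sample of the plateau). The cardiac TTL (`dTTL_ECG`,
#' duration `ttl_duration`) is raised at the sample that revealed the
#' turning point, i.e. one fast sample after the peak, and sampling reverts
#' to the base rate. Because the peak is located on the raw signal by
#' comparison of successive samples only, detection timing is independent of
#' the signal's amplitude and DC level. Re-arming is inhibited for
#' `refractory` ms from TTL onset; an armed search that finds no turning
#' point within `arm_timeout` ms disarms and is counted.
#'
#' @param trace The voltage-scaled ECG [waveform_trace()], sampled at the
#'   fast rate (its interval must equal `fast_sample_interval`).
#' @param cfg An [ecg_gate_config()].
#' @return An object of class `ecg_gate_result`: `detected_peaks` (ms),
#'   `ecg_ttl` (a [ttl_signal()] with one pulse per peak), `difference_trace`,
#'   `mode_switch_times` (data frame of arm/disarm times) and
#'   `arm_timeouts` (count).
#' @export
detect_r_waves <- function(trace, cfg = ecg_gate_config()) {
  stopifnot(inherits(trace, "waveform_trace"), inherits(cfg, "ecg_gate_config"))
  if (abs(trace$sample_interval - cfg$fast_sample_interval) > 1e-9) {
    stop("trace must be sampled at cfg$fast_sample_interval", call. = FALSE)
  }
  diff_trace <- ecg_difference(trace, cfg)
  dvals <- diff_trace$values
  dtimes <- trace_times(diff_trace)
  v <- trace$values
  t0 <- trace$start_time
  fdt <- cfg$fast_sample_interval
  n_fast <- length(v)
  fast_per_base <- as.integer(round(cfg$base_sample_interval / fdt))
  timeout_steps <- max(2L, ceiling(cfg$arm_timeout / fdt))

  # base samples whose difference exceeds the arming threshold
  cand <- which(dvals > cfg$arm_threshold)
  peaks <- numeric(0)
  ttl_start <- numeric(0)
  arm_t <- numeric(0); disarm_t <- numeric(0)
  timeouts <- 0L
  not_before <- -Inf   # earliest allowed next arming time (refractory)
  ci <- 1L
  while (ci <= length(cand)) {
    tb <- dtimes[cand[ci]]
    if (tb < not_before) {
      ci <- ci + 1L
      next
    }
    # fast sampling starts at the arming base sample
    j0 <- as.integer(round((tb - t0) / fdt)) + 1L
    j <- j0 + 1L
    plateau_start <- j0
    found <- FALSE
    while (j <= n_fast && (j - j0) < timeout_steps) {
      if (v[j] < v[j - 1L]) {
        found <- TRUE
        break
      }
      if (v[j] > v[j - 1L]) plateau_start <- j
      j <- j + 1L
    }
    if (found) {
      peak_t <- t0 + (plateau_start - 1L) * fdt
      det_t <- t0 + (j - 1L) * fdt      # sample that revealed the decrease
      peaks <- c(peaks, peak_t)
      ttl_start <- c(ttl_start, det_t)
      arm_t <- c(arm_t, tb); disarm_t <- c(disarm_t, det_t)
      not_before <- det_t + cfg$refractory
    } else {
      timeouts <- timeouts + 1L
      arm_t <- c(arm_t, tb)
      disarm_t <- c(disarm_t, t0 + (min(j, n_fast) - 1L) * fdt)
      not_before <- disarm_t[length(disarm_t)]
    }
    ci <- ci + 1L
  }
  window <- c(t0, trace_end(trace))
  iv <- if (length(ttl_start) > 0) {
    cbind(ttl_start, pmin(ttl_start + cfg$ttl_duration, window[2]))
  } else {
    matrix(numeric(0), ncol = 2)
  }
  structure(list(
    detected_peaks = peaks,
    ecg_ttl = ttl_signal(iv, label = "dTTL_ECG", window = window),
    difference_trace = diff_trace,
    mode_switch_times = data.frame(arm = arm_t, disarm = disarm_t),
    arm_timeouts = timeouts,
    config = cfg
  ), class = "ecg_gate_result")
}

#' @export
print.ecg_gate_result <- function(x, ...) {
  cat(sprintf("<ecg_gate_result> %d R-wave(s) detected, %d arm timeout(s)\n",
              length(x$detected_peaks), x$arm_timeouts))
  invisible(x)
}

#' Latency of the cardiac gate against ground truth
#'
#' Matches each detected R-wave to the nearest true (pre-amplifier) R-peak
#' within half a cardiac period and summarises the delay from the true peak
#' to the TTL onset. True peaks with no matched detection are misses;
#' detections with no true peak are false alarms.
#'
#' @param result An `ecg_gate_result` from [detect_r_waves()].
#' @param truth An [event_ground_truth()] with `r_peak_times`.
#' @param match_window Maximum |detection - truth| pairing distance, ms;
#'   defaults to half the median true R-R interval.
#' @return A list: `latencies` (per matched beat, ms, TTL onset minus true
#'   peak), `mean`, `max`, `n_matched`, `n_missed`, `n_false`.
#' @export
detection_latency <- function(result, truth, match_window = NULL) {
  stopifnot(inherits(result, "ecg_gate_result"),
            inherits(truth, "event_ground_truth"))
  true_pk <- truth$r_peak_times
  onsets <- result$ecg_ttl$high_intervals
  onsets <- if (nrow(onsets) > 0) onsets[, 1] else numeric(0)
  if (is.null(match_window)) {
    match_window <- if (length(true_pk) > 1) {
      stats::median(diff(true_pk)) / 2
    } else {
      Inf
    }
  }
  used <- logical(length(onsets))
  lat <- rep(NA_real_, length(true_pk))
  for (i in seq_along(true_pk)) {
    if (length(onsets) == 0) break
    d <- abs(onsets - true_pk[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= match_window) {
      lat[i] <- onsets[j] - true_pk[i]
      used[j] <- TRUE
    }
  }
  matched <- !is.na(lat)
  list(
    latencies = lat[matched],
    mean = if (any(matched)) mean(lat[matched]) else NA_real_,
    max = if (any(matched)) max(lat[matched]) else NA_real_,
    n_matched = sum(matched),
    n_missed = sum(!matched),
    n_false = sum(!used)
  )
}
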