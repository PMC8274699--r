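#' Ground-truth event times for a simulated physiological recording
#'
#' @param r_peak_times R-wave peak times, ms, strictly increasing.
#' @param breath_onset_times,breath_end_times Breath pulse onset/end times,
#'   ms; pairwise `end > onset`.
#' @return An object of class `event_ground_truth`.
#' @export
event_ground_truth <- function(r_peak_times = numeric(0),
                               breath_onset_times = numeric(0),
                               breath_end_times = numeric(0)) {
  chk <- function(x, name) {
    if (length(x) > 1 && any(diff(x) <= 0)) {
      stop(sprintf("%s must be strictly increasing", name), call. = FALSE)
    }
    as.numeric(x)
  }
  r <- chk(r_peak_times, "r_peak_times")
  bo <- chk(breath_onset_times, "breath_onset_times")
  be <- chk(breath_end_times, "breath_end_times")
  if (length(bo) != length(be) || any(be <= bo)) {
    stop("breath_end_times must pair with and exceed breath_onset_times",
         call. = FALSE)
  }
  structure(list(r_peak_times = r,
                 breath_onset_times = bo,
                 breath_end_times = be),
            class = "event_ground_truth")
}

#' @export
print.event_ground_truth <- function(x, ...) {
  cat(sprintf("<event_ground_truth> %d R-peaks, %d breaths\n",
              length(x$r_peak_times), length(x$breath_onset_times)))
  invisible(x)
}

# R-wave template evaluated at offsets `t` (ms) from the peak: a Gaussian of
# FWHM `width` flanked by two smaller negative lobes, giving the narrow
# positive spike with opposite-sign side lobes of a surface-electrode QRS.
r_wave_template <- function(t, width, amplitude) {
  sigma <- width / (2 * sqrt(2 * log(2)))
  lobe_sigma <- sigma / 1.5
  lobe_offset <- 1.6 * width
  amplitude * (exp(-t^2 / (2 * sigma^2)) -
                 0.25 * exp(-(t - lobe_offset)^2 / (2 * lobe_sigma^2)) -
                 0.25 * exp(-(t + lobe_offset)^2 / (2 * lobe_sigma^2)))
}

#' Peak-to-peak voltage of the simulated R-wave
#'
#' Used as the reference amplitude when scaling gradient-burst noise, which
#' the hardware literature quotes as a fraction of the R-wave peak-to-peak
#' voltage.
#'
#' @param params A [physio_params()].
#' @return Peak-to-peak template amplitude, volts.
#' @export
r_wave_p2p <- function(params) {
  t <- seq(-4 * params$r_wave_width, 4 * params$r_wave_width,
           by = 1 / (params$sample_rate / 1000))
  v <- r_wave_template(t, params$r_wave_width, params$r_wave_amplitude)
  max(v) - min(v)
}

# Draw event periods uniformly from mean +/- span until `duration` is covered.
draw_periods <- function(mean, span, duration) {
  n_guess <- ceiling(duration / max(mean - span, 1e-6)) + 2L
  periods <- numeric(0)
  total <- 0
  while (total < duration) {
    p <- stats::runif(n_guess, mean - span, mean + span)
    periods <- c(periods, p)
    total <- sum(periods)
  }
  periods
}

#' Simulate an ECG voltage trace
#'
#' Generates an ECG-like trace of R-wave peaks at the master sampling rate,
#' with successive R-R intervals drawn independently and uniformly from
#' `cardiac_period_mean +/- cardiac_period_span`. Each R-wave is a narrow
#' positive Gaussian spike (FWHM `r_wave_width`) flanked by smaller negative
#' lobes. If a respiration trace is supplied, it is coupled additively into
#' the ECG channel with gain `resp_coupling_gain`, providing the slow
#' respiration-induced voltage that the gate's difference filter must remove.
#'
#' @param params A [physio_params()].
#' @param duration Trace duration, ms; must exceed three cardiac periods.
#' @param seed Integer seed; identical inputs give bit-identical outputs.
#' @param resp_trace Optional respiration [waveform_trace()] on the same
#'   sampling grid to couple into the ECG baseline.
#' @return A list with elements `trace` ([waveform_trace()]) and `truth`
#'   ([event_ground_truth()] holding the exact R-peak times).
#' @export
simulate_cardiac <- function(params, duration, seed, resp_trace = NULL) {
  stopifnot(inherits(params, "physio_params"))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (duration <= 3 * params$cardiac_period_mean) {
    stop("duration must exceed three cardiac periods", call. = FALSE)
  }
  dt <- 1000 / params$sample_rate
  n <- floor(duration / dt) + 1L
  values <- numeric(n)
  peaks <- with_seed(seed, {
    periods <- draw_periods(params$cardiac_period_mean,
                            params$cardiac_period_span, duration)
    # first peak one period in, so the trace does not start mid-QRS
    p <- cumsum(periods)
    p[p <= duration - 4 * params$r_wave_width]
  })
  half_support <- 4 * params$r_wave_width
  for (pk in peaks) {
    i0 <- max(1L, floor((pk - half_support) / dt) + 1L)
    i1 <- min(n, ceiling((pk + half_support) / dt) + 1L)
    t <- (seq(i0, i1) - 1) * dt
    values[i0:i1] <- values[i0:i1] +
      r_wave_template(t - pk, params$r_wave_width, params$r_wave_amplitude)
  }
  if (!is.null(resp_trace) && params$resp_coupling_gain > 0) {
    if (abs(resp_trace$sample_interval - dt) > 1e-9) {
      stop("resp_trace must share the master sampling interval", call. = FALSE)
    }
    m <- min(n, length(resp_trace$values))
    values[seq_len(m)] <- values[seq_len(m)] +
      params$resp_coupling_gain * resp_trace$values[seq_len(m)]
  }
  list(
    trace = waveform_trace(values, dt, channel_label = "raw_ecg"),
    truth = event_ground_truth(r_peak_times = peaks)
  )
}

#' Simulate a respiration voltage trace
#'
#' Generates a train of unipolar positive breath pulses (raised-cosine shape,
#' duration `breath_pulse_width`, amplitude `breath_amplitude`) on a slow
#' sinusoidal baseline drift, with inter-onset periods drawn uniformly from
#' `resp_period_mean +/- resp_period_span`. The ground truth records the
#' onset and end of each pulse's support.
#'
#' @inheritParams simulate_cardiac
#' @return A list with elements `trace` and `truth` as in
#'   [simulate_cardiac()].
#' @export
simulate_respiration <- function(params, duration, seed) {
  stopifnot(inherits(params, "physio_params"))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (duration <= 3 * params$resp_period_mean) {
    stop("duration must exceed three respiration periods", call. = FALSE)
  }
  if (params$breath_pulse_width >= params$resp_period_mean - params$resp_period_span) {
    stop("breath pulses would overlap: breath_pulse_width too long", call. = FALSE)
  }
  dt <- 1000 / params$sample_rate
  n <- floor(duration / dt) + 1L
  times <- (seq_len(n) - 1) * dt
  onsets <- with_seed(seed, {
    periods <- draw_periods(params$resp_period_mean, params$resp_period_span,
                            duration)
    o <- cumsum(c(periods[1] / 2, periods[-1]))
    o[o <= duration - params$breath_pulse_width]
  })
  values <- if (params$baseline_drift_amplitude > 0) {
    params$baseline_drift_amplitude *
      sin(2 * pi * times / params$baseline_drift_period)
  } else {
    numeric(n)
  }
  w <- params$breath_pulse_width
  for (on in onsets) {
    i0 <- max(1L, floor(on / dt) + 2L)      # first sample strictly inside the pulse
    i1 <- min(n, floor((on + w) / dt) + 1L)
    if (i1 < i0) next
    t <- (seq(i0, i1) - 1) * dt
    values[i0:i1] <- values[i0:i1] +
      params$breath_amplitude * 0.5 * (1 - cos(2 * pi * (t - on) / w))
  }
  list(
    trace = waveform_trace(values, dt, channel_label = "raw_resp"),
    truth = event_ground_truth(breath_onset_times = onsets,
                               breath_end_times = onsets + w)
  )
}

#' Add TR-periodic gradient-burst noise to a trace
#'
#' Emulates pickup from the rapidly switched imaging gradients: a zero-mean
#' oscillatory burst (one full cosine cycle over `burst_width`) repeats every
#' `burst_period`, with peak-to-peak amplitude `fraction * reference_p2p`.
#' The burst waveform is identical from period to period, as the gradient
#' waveforms themselves are; the seed only randomises the phase of the burst
#' train relative to the trace (and, if `amplitude_jitter > 0`, scales each
#' burst by `1 + jitter` with uniform jitter in `+/- amplitude_jitter`).
#' The input trace is not modified.
#'
#' @param trace A [waveform_trace()].
#' @param burst_period Burst repetition period, ms (one per TR).
#' @param burst_width Burst duration, ms; must be shorter than the period.
#' @param fraction Noise peak-to-peak as a fraction of `reference_p2p`.
#' @param reference_p2p Reference peak-to-peak voltage (normally the R-wave's,
#'   see [r_wave_p2p()]).
#' @param seed Integer seed.
#' @param amplitude_jitter Half-width of the uniform per-burst amplitude
#'   jitter, dimensionless (default 0 = strictly periodic bursts).
#' @return A new [waveform_trace()] with the noise added.
#' @export
add_gradient_noise <- function(trace, burst_period = 4, burst_width = 1,
                               fraction = 0.2, reference_p2p = 1, seed = 1,
                               amplitude_jitter = 0) {
  stopifnot(inherits(trace, "waveform_trace"))
  stopifnot_scalar(fraction, "fraction", nonneg = TRUE)
  stopifnot_scalar(burst_period, "burst_period", positive = TRUE)
  stopifnot_scalar(burst_width, "burst_width", positive = TRUE)
  stopifnot_scalar(reference_p2p, "reference_p2p", positive = TRUE)
  stopifnot_scalar(amplitude_jitter, "amplitude_jitter", nonneg = TRUE)
  if (burst_period <= burst_width) {
    stop("burst_period must exceed burst_width", call. = FALSE)
  }
  if (fraction == 0) return(trace)
  dt <- trace$sample_interval
  if (burst_period / dt < 2) {
    stop("trace sampling too coarse for the requested burst_period", call. = FALSE)
  }
  n <- length(trace$values)
  times <- (seq_len(n) - 1) * dt
  amp <- fraction * reference_p2p / 2
  noise <- with_seed(seed, {
    # phase offset snapped to the sampling grid, so the burst extrema are hit
    # exactly and the added component's peak-to-peak equals fraction * ref
    phase0 <- floor(stats::runif(1, 0, burst_period) / dt) * dt
    tt <- (times + phase0) %% burst_period
    inside <- tt < burst_width
    v <- numeric(n)
    v[inside] <- amp * cos(2 * pi * tt[inside] / burst_width)
    if (amplitude_jitter > 0) {
      burst_id <- floor((times + phase0) / burst_period)
      ids <- unique(burst_id[inside])
      jit <- 1 + stats::runif(length(ids), -amplitude_jitter, amplitude_jitter)
      v[inside] <- v[inside] * jit[match(burst_id[inside], ids)]
    }
    v
  })
  out <- trace
  out$values <- trace$values + noise
  out
}

#' Write / read ground-truth event times as JSON
#'
#' Keys: `r_peak_times_ms`, `breath_onset_times_ms`, `breath_end_times_ms`.
#'
#' @param truth An [event_ground_truth()].
#' @param path File path.
#' @return `write_ground_truth_json()` returns `path` invisibly;
#'   `read_ground_truth_json()` returns an [event_ground_truth()].
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    r_peak_times_ms = truth$r_peak_times,
    breath_onset_times_ms = truth$breath_onset_times,
    breath_end_times_ms = truth$breath_end_times
  ), path, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  event_ground_truth(
    r_peak_times = as.numeric(obj$r_peak_times_ms),
    breath_onset_times = as.numeric(obj$breath_onset_times_ms),
    breath_end_times = as.numeric(obj$breath_end_times_ms)
  )
}
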