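# Shared fixtures, built in code.

# One clean conditioned ECG recording with ground truth, reused by several
# detector tests. `delay` is the amplifier propagation delay in ms.
make_clean_ecg <- function(duration = 5000, seed = 42, delay = 4,
                           smoothing = 4.5, params = physio_params()) {
  sim <- simulate_cardiac(params, duration, seed)
  amp <- apply_amplifier(sim$trace,
                         amplifier_model(propagation_delay = delay,
                                         smoothing_width = smoothing))
  scaled <- scale_voltage(amp)
  list(sim = sim, scaled = scaled, params = params)
}

# Conditioned respiration recording.
make_clean_resp <- function(duration = 20000, seed = 42,
                            params = physio_params()) {
  sim <- simulate_respiration(params, duration, seed)
  amp <- apply_amplifier(sim$trace, resp_amplifier_model())
  scaled <- scale_voltage(amp)
  list(sim = sim, scaled = scaled, params = params)
}

# TTL pulse train at given onset times (8 ms pulses by default). The default
# window ends shortly after the last pulse: the monitored stream is over.
pulse_train <- function(onsets, width = 8, window = NULL) {
  if (is.null(window)) window <- c(0, max(onsets) + width + 50)
  ttl_signal(cbind(onsets, onsets + width), window = window)
}

# Independent breath-declaration oracle: scan the gaps of a completed
# schedule for runs of gate-evaluation ticks longer than the threshold.
brute_force_declarations <- function(schedule) {
  p <- schedule$params
  starts <- schedule$blocks$start_time
  ends <- starts + p$n_frames * p$tr
  gap_ticks <- c(
    round((starts[1] - schedule$window[1]) / p$tr),
    if (length(starts) > 1) round((starts[-1] - ends[-length(ends)]) / p$tr)
  )
  sum(gap_ticks > p$breath_count_threshold)
}
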