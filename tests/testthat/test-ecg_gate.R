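test_that("ECG difference zeroes constants and bounds slow sinusoids", {
  cfg <- ecg_gate_config()
  const <- waveform_trace(rep(3, 5000), 0.1)
  expect_true(all(ecg_difference(const, cfg)$values == 0))

  # 1 s period, 0.5 V amplitude: |diff over 4 ms| <= 2*pi*4/1000*0.5
  t <- seq(0, 3000, by = 0.1)
  slow <- waveform_trace(0.5 * sin(2 * pi * t / 1000), 0.1)
  d <- ecg_difference(slow, cfg)$values
  expect_lte(max(abs(d)), 2 * pi * 4 / 1000 * 0.5 + 1e-12)

  expect_error(ecg_difference(waveform_trace(c(1, 2), 1), cfg), "lag")
})

test_that("the R-wave rising edge produces a large step in the difference", {
  params <- physio_params(resp_coupling_gain = 0)
  sim <- simulate_cardiac(params, 1000, seed = 1)
  d <- ecg_difference(sim$trace, ecg_gate_config())
  expect_gt(max(d$values), params$r_wave_amplitude / 2)
})

test_that("noise-free detection localises every peak to within one fast sample", {
  ecg <- make_clean_ecg(duration = 10000, seed = 13)
  res <- detect_r_waves(ecg$scaled)
  truth <- ecg$sim$truth$r_peak_times
  expect_equal(length(res$detected_peaks), length(truth))
  expect_equal(res$arm_timeouts, 0L)

  # oracle: per-beat argmax of the conditioned trace the detector sees
  times <- trace_times(ecg$scaled)
  fdt <- ecg$scaled$sample_interval
  for (pk in res$detected_peaks) {
    win <- which(times > pk - 20 & times < pk + 20)
    t_argmax <- times[win[which.max(ecg$scaled$values[win])]]
    expect_lt(abs(pk - t_argmax), fdt + 1e-9)
  }
})

test_that("detection times are invariant to DC offset and amplitude scaling", {
  ecg <- make_clean_ecg(duration = 6000, seed = 17)
  base <- detect_r_waves(ecg$scaled)
  shifted <- ecg$scaled
  shifted$values <- shifted$values + 0.8
  scaled2 <- ecg$scaled
  scaled2$values <- 2.5 + (scaled2$values - 2.5) * 1.5
  cfg <- ecg_gate_config()
  expect_equal(detect_r_waves(shifted, cfg)$detected_peaks, base$detected_peaks)
  expect_equal(detect_r_waves(scaled2, cfg)$detected_peaks, base$detected_peaks)
})

test_that("gaps between detections respect the refractory period", {
  ecg <- make_clean_ecg(duration = 20000, seed = 19)
  for (refr in c(16, 40)) {
    res <- detect_r_waves(ecg$scaled, ecg_gate_config(refractory = refr))
    onsets <- res$ecg_ttl$high_intervals[, 1]
    if (length(onsets) > 1) expect_gte(min(diff(onsets)), refr)
  }
})

test_that("an arming threshold above the R-wave step yields no detections", {
  ecg <- make_clean_ecg(duration = 3000, seed = 23)
  res <- detect_r_waves(ecg$scaled, ecg_gate_config(arm_threshold = 4.9))
  expect_equal(length(res$detected_peaks), 0)
  expect_equal(nrow(res$ecg_ttl$high_intervals), 0)
  lat <- detection_latency(res, ecg$sim$truth)
  expect_equal(lat$n_missed, length(ecg$sim$truth$r_peak_times))
  expect_equal(length(lat$latencies), 0)
})

test_that("latency stays within two fast samples of the amplifier delay on clean signals", {
  # zero amplifier delay: only the turning-point mechanism delays the TTL
  ecg0 <- make_clean_ecg(duration = 6000, seed = 29, delay = 0, smoothing = 0)
  res0 <- detect_r_waves(ecg0$scaled)
  lat0 <- detection_latency(res0, ecg0$sim$truth)
  expect_equal(lat0$n_missed, 0)
  expect_lte(lat0$max, 2 * 0.1 + 1e-9)

  # 3.5 ms delay: total synchrony under 4 ms
  ecg35 <- make_clean_ecg(duration = 6000, seed = 29, delay = 3.5)
  lat35 <- detection_latency(detect_r_waves(ecg35$scaled), ecg35$sim$truth)
  expect_equal(lat35$n_missed, 0)
  expect_lt(lat35$max, 4)
})

test_that("flat-topped peaks resolve to the first plateau sample", {
  dt <- 0.1
  n <- 4000
  v <- rep(0, n)
  # trapezoid: rise over 2 ms, flat for 1 ms, fall
  rise <- seq(0, 3, length.out = 21)
  i0 <- 2001
  v[i0:(i0 + 20)] <- rise
  v[(i0 + 21):(i0 + 30)] <- 3
  v[(i0 + 31):(i0 + 51)] <- rev(seq(0, 3, length.out = 21))
  trace <- waveform_trace(v, dt)
  res <- detect_r_waves(trace, ecg_gate_config(arm_threshold = 0.5))
  expect_equal(length(res$detected_peaks), 1)
  expect_equal(res$detected_peaks, (i0 + 20 - 1) * dt)
})

test_that("gate combination is an interval intersection with edge truncation", {
  acquire <- ttl_signal(cbind(c(0, 1200), c(1008, 2000)), window = c(0, 2000),
                        label = "acq")
  ecg <- ttl_signal(cbind(c(100, 1000, 1100, 1500), c(116, 1016, 1116, 1516)),
                    window = c(0, 2000), label = "ecg")
  out <- combine_gates(ecg, acquire)
  expect_equal(unname(out$high_intervals),
               matrix(c(100, 116, 1000, 1008, 1500, 1516),
                      ncol = 2, byrow = TRUE))
  # mismatched polarity is refused
  expect_error(combine_gates(flip_polarity(ecg), acquire), "polarity")
})

test_that("end-to-end latency summary matches a hand-built scenario", {
  truth <- event_ground_truth(r_peak_times = c(100, 234, 368))
  fake <- structure(list(
    detected_peaks = c(101, 235.2),
    ecg_ttl = ttl_signal(cbind(c(101.1, 235.3), c(117.1, 251.3)),
                         window = c(0, 500)),
    difference_trace = waveform_trace(0, 1),
    mode_switch_times = data.frame(arm = numeric(0), disarm = numeric(0)),
    arm_timeouts = 0L
  ), class = "ecg_gate_result")
  lat <- detection_latency(fake, truth)
  expect_equal(lat$n_matched, 2)
  expect_equal(lat$n_missed, 1)
  expect_equal(lat$n_false, 0)
  expect_equal(lat$latencies, c(1.1, 1.3), tolerance = 1e-9)
  expect_equal(lat$max, 1.3, tolerance = 1e-9)
})
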