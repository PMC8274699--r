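test_that("differential zeroes constants, ramps and suppresses slow drift", {
  cfg <- resp_gate_config()
  const <- waveform_trace(rep(2.5, 100), 10)
  expect_true(all(resp_differential(const, cfg)$values == 0))

  ramp <- waveform_trace(0.003 * seq(0, 990, by = 10), 10)
  d <- resp_differential(ramp, cfg)$values
  expect_equal(d[-1], rep(0.003 * 10, 99), tolerance = 1e-12)

  # 30 s period, 1 V sinusoid: |diff| bounded by 2*pi*10/30000 V
  t <- seq(0, 60000, by = 10)
  slow <- waveform_trace(sin(2 * pi * t / 30000), 10)
  d <- resp_differential(slow, cfg)$values
  expect_lte(max(abs(d)), 2 * pi * 10 / 30000 + 1e-12)

  expect_error(resp_differential(waveform_trace(1, 10), cfg), "2 samples")
})

test_that("termination level is onset plus the trailing fraction of the excursion", {
  # craft a trace whose differential walks 0,1,2,3,2,1.2,0.5,...
  diffs <- c(0, 0, 1, 2, 3, 2, 1.2, 0.5, 0, 0, 0)
  trace <- waveform_trace(cumsum(diffs), 10)
  cfg <- resp_gate_config(threshold = 1, trailing_fraction = 0.2)
  res <- detect_breaths(trace, cfg)
  expect_equal(nrow(res$breaths), 1)
  expect_equal(res$breaths$onset_value, 1)
  expect_equal(res$breaths$max_value, 3)
  expect_equal(res$breaths$termination_level, 1 + 0.2 * (3 - 1))
  # ends at the first sample below 1.4 (the 1.2 sample)
  expect_equal(res$breaths$end_time, 60)
})

test_that("a trace that never crosses threshold yields one full acquire window", {
  trace <- waveform_trace(rep(0.1, 200), 10)
  res <- detect_breaths(trace, resp_gate_config(threshold = 1))
  expect_equal(nrow(res$breaths), 0)
  expect_equal(nrow(res$threshold_ttl$high_intervals), 0)
  acq <- res$acquire_ttl$high_intervals
  expect_equal(nrow(acq), 1)
  expect_equal(acq[1, ], c(start = 0, end = 1990))
})

test_that("every simulated breath is detected, with no false positives", {
  resp <- make_clean_resp(duration = 60000, seed = 21)
  res <- detect_breaths(resp$scaled, resp_gate_config())
  expect_equal(nrow(res$breaths), length(resp$sim$truth$breath_onset_times))
  # detections land within the (delayed) breath support: onset must fall
  # between true onset and true end + amplifier delay + one grid step
  delay <- resp_amplifier_model()$propagation_delay
  for (i in seq_len(nrow(res$breaths))) {
    on <- res$breaths$onset_time[i]
    truth_on <- resp$sim$truth$breath_onset_times[i]
    truth_end <- resp$sim$truth$breath_end_times[i]
    expect_gte(on, truth_on)
    expect_lte(on, truth_end + delay + 60)
  }
})

test_that("acquire and no-acquire windows tile the timeline without overlap", {
  for (seed in c(1, 2)) {
    resp <- make_clean_resp(duration = 30000, seed = seed)
    res <- detect_breaths(resp$scaled, resp_gate_config())
    w <- res$acquire_ttl$window
    probe <- seq(w[1], w[2] - 0.5, length.out = 4001)
    in_acq <- ttl_is_high(res$acquire_ttl, probe)
    in_na <- ttl_is_high(res$no_acquire_ttl, probe)
    expect_true(all(xor(in_acq, in_na)))
    # threshold pulses live inside no-acquire windows
    thr <- res$threshold_ttl$high_intervals
    mid <- (thr[, 1] + thr[, 2]) / 2
    expect_true(all(ttl_is_high(res$no_acquire_ttl, mid)))
    expect_true(all(ttl_is_high(res$no_acquire_ttl, thr[, 1])))
  }
})

test_that("raising the no-acquire extension never shrinks any no-acquire window", {
  resp <- make_clean_resp(duration = 30000, seed = 4)
  total_na <- sapply(c(0, 50, 150, 300, 600), function(ext) {
    res <- detect_breaths(resp$scaled, resp_gate_config(no_acquire_extension = ext))
    iv <- res$no_acquire_ttl$high_intervals
    sum(iv[, 2] - iv[, 1])
  })
  expect_true(all(diff(total_na) >= -1e-9))
})

test_that("manual acquire shortening truncates windows and keeps the tiling", {
  resp <- make_clean_resp(duration = 30000, seed = 4)
  res <- detect_breaths(resp$scaled, resp_gate_config(acquire_max_duration = 400))
  acq <- res$acquire_ttl$high_intervals
  expect_true(all(acq[, 2] - acq[, 1] <= 400 + 1e-9))
  w <- res$acquire_ttl$window
  probe <- seq(w[1], w[2] - 0.5, length.out = 2001)
  expect_true(all(xor(ttl_is_high(res$acquire_ttl, probe),
                      ttl_is_high(res$no_acquire_ttl, probe))))
})

test_that("slope mode triggers on the leading edge and terminates on the voltage", {
  # symmetric triangular breath over a flat baseline
  dt <- 10
  rise <- seq(0, 2, length.out = 21)
  v <- c(rep(0, 20), rise, rev(rise)[-1], rep(0, 40))
  trace <- waveform_trace(v, dt)
  slope_cfg <- resp_gate_config(threshold = 0.005, mode = "slope")
  amp_cfg <- resp_gate_config(threshold = 0.08)
  res_slope <- slope_trigger(trace, slope_cfg)
  res_amp <- detect_breaths(trace, amp_cfg)
  expect_equal(nrow(res_slope$breaths), 1)
  expect_equal(nrow(res_amp$breaths), 1)
  expect_lte(res_slope$breaths$onset_time, res_amp$breaths$onset_time)
  # termination: voltage falls through onset + 0.2 * (peak - onset)
  b <- res_slope$breaths
  lvl <- b$onset_value + 0.2 * (b$max_value - b$onset_value)
  t_end_idx <- round(b$end_time / dt) + 1
  expect_lt(v[t_end_idx], lvl)
  expect_gte(v[t_end_idx - 1], lvl)
})

test_that("slope mode on clean pulse trains detects one onset per breath, increasing", {
  resp <- make_clean_resp(duration = 30000, seed = 8)
  res <- slope_trigger(resp$scaled, resp_gate_config(threshold = 0.004, mode = "slope"))
  expect_equal(nrow(res$breaths), length(resp$sim$truth$breath_onset_times))
  expect_true(all(diff(res$breaths$onset_time) > 0))
})

test_that("a pulse whose trailing edge never crosses the level is force-terminated", {
  # staircase: differential rises then stays put, never falling through
  diffs <- c(0, 0, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2)
  trace <- waveform_trace(cumsum(diffs), 10)
  cfg <- resp_gate_config(threshold = 1, termination_timeout = 50)
  expect_message(res <- detect_breaths(trace, cfg), "force-terminated")
  expect_true(res$breaths$timed_out[1])
  expect_lte(res$breaths$end_time - res$breaths$onset_time, 50 + 1e-9)
})

test_that("TTL JSON round trips exactly and polarity flip complements the window", {
  ttl <- ttl_signal(cbind(c(10, 50), c(20, 60)), label = "t", window = c(0, 100))
  path <- withr::local_tempfile(fileext = ".json")
  write_ttl_json(ttl, path)
  expect_equal(read_ttl_json(path), ttl)

  flipped <- flip_polarity(ttl)
  expect_equal(flipped$polarity, "low_means_acquire")
  expect_equal(flipped$high_intervals,
               matrix(c(0, 10, 20, 50, 60, 100), ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("start", "end"))))
  expect_equal(as_acquire_high(flipped), ttl_signal(ttl$high_intervals,
                                                    label = "t", window = c(0, 100)))
})
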