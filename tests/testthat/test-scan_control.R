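test_that("breath declaration re-queues the two preceding blocks and completes", {
  params <- scan_params(n_phase_encodes = 6)
  # six triggered blocks, a long silence, then triggers for the re-acquisitions
  onsets <- c(0, 100, 200, 300, 400, 500, 800, 900)
  sch <- run_scan(pulse_train(onsets), params)
  expect_true(sch$complete)
  # breath declared on the 26th consecutive gate tick after block 5 ends (580)
  expect_equal(sch$breath_declarations, 580 + 25 * 4)
  expect_equal(sum(sch$blocks$status == "discarded_reacquired"), 2)
  redone <- sch$blocks$phase_encode_index[sch$blocks$status == "discarded_reacquired"]
  expect_equal(sort(redone), c(4, 5))
  # re-queued lines acquired first once triggers resume, in original order
  post <- sch$blocks[sch$blocks$start_time >= 800, ]
  expect_equal(post$phase_encode_index, c(4, 5))
  kept <- sch$blocks$phase_encode_index[sch$blocks$status == "kept"]
  expect_equal(sort(kept), 0:5)
  s <- scan_time_summary(sch)
  expect_equal(s$kept_blocks, 6)
  expect_equal(s$reacquired_blocks, 2)
  expect_equal(s$breaths_declared, 1)
})

test_that("exactly 25 gate ticks do not declare a breath (strict threshold)", {
  params <- scan_params(n_phase_encodes = 2)
  # block 0 at t=0 ends at 80; 25 gate ticks at 80..176; trigger at 180
  sch <- run_scan(pulse_train(c(0, 180)), params)
  expect_equal(length(sch$breath_declarations), 0)
  expect_equal(sum(sch$blocks$status == "discarded_reacquired"), 0)
  # one tick more does declare (and re-queues the only existing block)
  sch2 <- run_scan(pulse_train(c(0, 184, 284, 384)), scan_params(n_phase_encodes = 2))
  expect_equal(length(sch2$breath_declarations), 1)
  expect_true(sch2$complete)
})

test_that("an always-high gate gives back-to-back blocks and constant-TR RF", {
  params <- scan_params(n_phase_encodes = 8)
  ttl <- ttl_signal(cbind(0, 1e6), window = c(0, 1e6))
  sch <- run_scan(ttl, params)
  expect_true(sch$complete)
  expect_equal(length(sch$breath_declarations), 0)
  expect_equal(sch$blocks$start_time, (0:7) * 80)
  expect_equal(sch$total_duration, 8 * 80)
  # tSSM constant-TR contract
  expect_true(all(abs(diff(sch$rf_pulse_times) - params$tr) < 1e-9))
})

test_that("the TR clock quantizes trigger onsets into uniform first-frame jitter", {
  tr <- 4; ne <- 20
  n <- 10000
  base <- cumsum(rep((ne + 6) * tr, n))
  set.seed(101)
  onsets <- base + runif(n, 0, tr)
  ttl <- pulse_train(onsets, width = 8)
  sch <- run_scan(ttl, scan_params(n_phase_encodes = n))
  js <- trigger_jitter_stats(sch)
  expect_equal(length(js$delays), n)
  expect_true(all(js$delays >= 0 & js$delays <= tr))
  expect_equal(js$mean_delay_tr, 0.5, tolerance = 0.02)
  expect_gt(js$uniformity_p, 0.01)

  # phase-locked triggers: all delays equal
  locked <- pulse_train(cumsum(rep((ne + 6) * tr, 50)) + 1.5, width = 8)
  js2 <- trigger_jitter_stats(run_scan(locked, scan_params(n_phase_encodes = 50)))
  expect_equal(diff(range(js2$delays)), 0)
})

test_that("breath declaration matches a brute-force gap scan on random streams", {
  set.seed(7)
  for (rep_i in 1:5) {
    gaps <- sample(c(20, 60, 120, 160, 200), 60, replace = TRUE)
    onsets <- cumsum(80 + gaps)
    n_enc <- 30
    ttl <- pulse_train(onsets, width = 8)
    sch <- suppressWarnings(run_scan(ttl, scan_params(n_phase_encodes = n_enc)))
    expect_equal(length(sch$breath_declarations), brute_force_declarations(sch))
    # conservation: kept + discarded = launched
    expect_equal(sum(sch$blocks$status == "kept") +
                   sum(sch$blocks$status == "discarded_reacquired"),
                 nrow(sch$blocks))
  }
})

test_that("re-acquisition conservation holds when breaths are well separated", {
  onsets <- c()
  t <- 0
  for (b in 1:4) {
    onsets <- c(onsets, t + (0:5) * 100)   # six blocks between breaths
    t <- t + 6 * 100 + 300                 # then a 300 ms silence (a breath)
  }
  onsets <- c(onsets, t + (0:3) * 100)
  sch <- run_scan(pulse_train(onsets), scan_params(n_phase_encodes = 20))
  expect_true(sch$complete)
  expect_equal(sum(sch$blocks$status == "discarded_reacquired"),
               2 * length(sch$breath_declarations))
})

test_that("a gate that never opens raises an error; short pulses warn", {
  ttl <- ttl_signal(matrix(numeric(0), ncol = 2), window = c(0, 5000))
  expect_error(run_scan(ttl, scan_params(n_phase_encodes = 2)), "never went high")
  short <- ttl_signal(cbind(c(0, 100), c(2, 102)), window = c(0, 400))
  expect_warning(try(run_scan(short, scan_params(n_phase_encodes = 1)), silent = TRUE),
                 "shorter than one TR")
})

test_that("cCRT suspends RF between blocks and mixes repetition times", {
  ne <- 20; tr <- 4; rr <- 134
  onsets <- (0:39) * rr
  ecg <- pulse_train(onsets, width = 16)
  acq <- ttl_signal(cbind(0, 1e5), window = c(0, 1e5))
  sch <- run_scan_ccrt(ecg, acq, scan_params(n_phase_encodes = 30, mode = "ccrt"))
  expect_true(sch$complete)
  expect_equal(nrow(sch$blocks), 30)
  # RF only during blocks: count = 30 * NE
  expect_equal(length(sch$rf_pulse_times), 30 * ne)
  gaps <- diff(sch$rf_pulse_times)
  expect_equal(sort(unique(round(gaps, 9))), c(tr, rr - (ne - 1) * tr))
  # hiatus between block end and next trigger
  hiatus <- sch$blocks$start_time[-1] - (sch$blocks$start_time[-30] + ne * tr)
  expect_true(all(abs(hiatus - (rr - ne * tr)) < 1e-9))

  # a breath spanning three beats suspends blocks entirely
  acq2 <- ttl_signal(cbind(c(0, 700), c(380, 1e5)), window = c(0, 1e5))
  sch2 <- run_scan_ccrt(ecg, acq2, scan_params(n_phase_encodes = 10, mode = "ccrt"))
  trig <- sch2$blocks$trigger_time
  expect_false(any(trig >= 380 & trig < 700))
})

test_that("DG pulses RF after every beat and goes hiatus-free when R-R = NE*TR", {
  ne <- 20; tr <- 4
  # R-R exactly NE*TR: RF timing collapses to constant TR
  onsets <- (0:29) * (ne * tr)
  sch <- run_scan_dg(pulse_train(onsets, width = 16),
                     scan_params(n_phase_encodes = 30, mode = "dg"))
  expect_true(all(abs(diff(sch$rf_pulse_times) - tr) < 1e-9))

  # R-R 134: hiatus of 54 ms per beat
  onsets2 <- (0:29) * 134
  sch2 <- run_scan_dg(pulse_train(onsets2, width = 16),
                      scan_params(n_phase_encodes = 30, mode = "dg"))
  hiatus <- sch2$blocks$start_time[-1] - (sch2$blocks$start_time[-30] + ne * tr)
  expect_true(all(abs(hiatus - 54) < 1e-9))

  # deleting one trigger doubles one inter-block interval
  onsets3 <- onsets2[-15]
  sch3 <- suppressWarnings(run_scan_dg(pulse_train(onsets3, width = 16),
                                       scan_params(n_phase_encodes = 29, mode = "dg")))
  gaps <- diff(sch3$blocks$start_time)
  expect_equal(max(gaps), 2 * 134)

  # blocks during breaths run RF but carry no data
  acq <- ttl_signal(cbind(c(0, 500), c(380, 1e5)), window = c(0, 1e5))
  sch4 <- run_scan_dg(pulse_train(onsets2, width = 16),
                      scan_params(n_phase_encodes = 27, mode = "dg"),
                      resp_acquire_ttl = acq)
  nod <- sch4$blocks[sch4$blocks$status == "no_data", ]
  expect_gt(nrow(nod), 0)
  expect_true(all(nod$trigger_time >= 380 & nod$trigger_time < 500))
  expect_equal(sort(sch4$blocks$phase_encode_index[sch4$blocks$status == "kept"]),
               0:26)
})

test_that("centre-out localiser ordering starts at the k-space centre", {
  ord <- centre_out_order(8)
  expect_equal(ord[1:3], c(4, 3, 5))
  expect_equal(sort(ord), 0:7)
  ord5 <- centre_out_order(5)
  expect_equal(ord5[1], 2)
  # an explicit ordering is honoured by the scheduler
  ttl <- ttl_signal(cbind(0, 1e5), window = c(0, 1e5))
  sch <- run_scan(ttl, scan_params(n_phase_encodes = 8), order = centre_out_order(8))
  expect_equal(sch$blocks$phase_encode_index, ord)
})

test_that("incomplete schedules are flagged and refuse a summary", {
  ttl <- pulse_train(c(0, 100), width = 8, window = c(0, 400))
  sch <- suppressWarnings(run_scan(ttl, scan_params(n_phase_encodes = 5),
                                   max_duration = 400))
  expect_false(sch$complete)
  expect_error(scan_time_summary(sch), "missing phase encode")
})

test_that("schedules round trip through JSON lines", {
  sch <- run_scan(pulse_train(c(0, 100, 200)), scan_params(n_phase_encodes = 3))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_schedule_jsonl(sch, path)
  back <- read_schedule_jsonl(path)
  expect_equal(back$phase_encode_index, sch$blocks$phase_encode_index)
  expect_equal(back$trigger_time, sch$blocks$trigger_time)
  expect_equal(back$start_time, sch$blocks$start_time)
  expect_equal(back$status, sch$blocks$status)
})
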