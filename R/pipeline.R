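#' Full run configuration
#'
#' Bundles every tunable quantity of the end-to-end simulation into one
#' nested object, so a run is fully reproducible from its configuration and
#' seed. Any component left `NULL` takes that component's documented default.
#'
#' @param physio A [physio_params()].
#' @param ecg_amplifier,resp_amplifier [amplifier_model()]s for the two
#'   channels.
#' @param scaler A [scaler_config()].
#' @param resp_gate A [resp_gate_config()].
#' @param ecg_gate An [ecg_gate_config()].
#' @param scan A [scan_params()].
#' @param tissue A [tissue_params()].
#' @param sequence A [sequence_params()].
#' @param duration Simulated recording duration, ms.
#' @param seed Integer master seed.
#' @param gradient_noise Logical: add gradient-burst noise to the ECG channel
#'   (amplitude from `physio$gradient_noise_fraction`, one burst per scan TR)?
#' @return An object of class `run_config`.
#' @export
run_config <- function(physio = physio_params(),
                       ecg_amplifier = amplifier_model(),
                       resp_amplifier = resp_amplifier_model(),
                       scaler = scaler_config(),
                       resp_gate = resp_gate_config(),
                       ecg_gate = ecg_gate_config(),
                       scan = scan_params(),
                       tissue = tissue_params(),
                       sequence = sequence_params(),
                       duration = 60000,
                       seed = 1) {
  stopifnot(inherits(physio, "physio_params"),
            inherits(ecg_amplifier, "amplifier_model"),
            inherits(resp_amplifier, "amplifier_model"),
            inherits(scaler, "scaler_config"),
            inherits(resp_gate, "resp_gate_config"),
            inherits(ecg_gate, "ecg_gate_config"),
            inherits(scan, "scan_params"),
            inherits(tissue, "tissue_params"),
            inherits(sequence, "sequence_params"))
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(seed, "seed")
  structure(list(
    physio = physio,
    ecg_amplifier = ecg_amplifier,
    resp_amplifier = resp_amplifier,
    scaler = scaler,
    resp_gate = resp_gate,
    ecg_gate = ecg_gate,
    scan = scan,
    tissue = tissue,
    sequence = sequence,
    duration = duration,
    seed = as.integer(seed)
  ), class = "run_config")
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass(rapply(config, unclass, how = "replace")),
                              auto_unbox = TRUE, digits = NA, force = TRUE))
}

#' Run the complete gating + acquisition pipeline
#'
#' End-to-end composition of the package's modules: synthetic physiology
#' (respiration and ECG with ground truth), amplifier conditioning,
#' gradient-burst noise on the ECG, voltage scaling, respiratory and cardiac
#' gate state machines, Boolean AND combination, the gated CINE scan in the
#' configured mode, and magnetization evolution. Deterministic given
#' `config$seed`.
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, traces (CSV), gate
#'   signals (JSON), ground truth (JSON), the schedule (JSON lines), the
#'   magnetization series (CSV) and a summary (JSON, stamped with seed and a
#'   configuration hash) are written there.
#' @return A list with all intermediate products: `resp`, `ecg` (raw trace +
#'   truth), `resp_scaled`, `ecg_scaled`, `resp_result`, `ecg_result`,
#'   `cr_ttl`, `schedule`, `magnetization`, `stability` and `summary`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seed <- config$seed
  resp <- stage("physio_sim/respiration",
                simulate_respiration(config$physio, config$duration, seed))
  ecg <- stage("physio_sim/cardiac",
               simulate_cardiac(config$physio, config$duration, seed + 1L,
                                resp_trace = resp$trace))
  resp_amp <- stage("conditioning/resp",
                    apply_amplifier(resp$trace, config$resp_amplifier))
  ecg_amp <- stage("conditioning/ecg",
                   apply_amplifier(ecg$trace, config$ecg_amplifier))
  if (config$physio$gradient_noise_fraction > 0) {
    ecg_amp <- stage("physio_sim/gradient_noise", add_gradient_noise(
      ecg_amp,
      burst_period = config$scan$tr, burst_width = min(1, config$scan$tr / 2),
      fraction = config$physio$gradient_noise_fraction,
      reference_p2p = r_wave_p2p(config$physio),
      seed = seed + 2L
    ))
  }
  resp_scaled <- stage("conditioning/scale_resp",
                       scale_voltage(resp_amp, config$scaler))
  ecg_scaled <- stage("conditioning/scale_ecg",
                      scale_voltage(ecg_amp, config$scaler))
  resp_result <- stage("resp_gate", detect_breaths(resp_scaled, config$resp_gate))
  ecg_result <- stage("ecg_gate", detect_r_waves(ecg_scaled, config$ecg_gate))
  cr_ttl <- stage("combine_gates",
                  combine_gates(ecg_result$ecg_ttl, resp_result$acquire_ttl))
  schedule <- stage("scan_control", switch(
    config$scan$mode,
    tssm = run_scan(cr_ttl, config$scan),
    ccrt = run_scan_ccrt(ecg_result$ecg_ttl, resp_result$acquire_ttl, config$scan),
    dg = run_scan_dg(ecg_result$ecg_ttl, config$scan,
                     resp_acquire_ttl = resp_result$acquire_ttl)
  ))
  record <- stage("magnetization",
                  evolve_magnetization(schedule, config$tissue, config$sequence))
  stability <- tryCatch(stability_metrics(record),
                        error = function(e) list(short_term_cv = NA_real_,
                                                 long_term_cv = NA_real_))
  latency <- stage("detection_latency", detection_latency(ecg_result, ecg$truth))
  summary <- list(
    seed = seed,
    config_hash = config_hash(config),
    mode = config$scan$mode,
    duration_ms = config$duration,
    true_beats = length(ecg$truth$r_peak_times),
    detected_beats = length(ecg_result$detected_peaks),
    missed_beats = latency$n_missed,
    false_detections = latency$n_false,
    max_latency_ms = latency$max,
    mean_latency_ms = latency$mean,
    true_breaths = length(resp$truth$breath_onset_times),
    detected_breaths = nrow(resp_result$breaths),
    scan_complete = schedule$complete,
    scan_duration_ms = schedule$total_duration,
    kept_blocks = sum(schedule$blocks$status == "kept"),
    reacquired_blocks = sum(schedule$blocks$status == "discarded_reacquired"),
    breaths_declared = length(schedule$breath_declarations),
    short_term_cv = stability$short_term_cv,
    long_term_cv = stability$long_term_cv
  )
  out <- list(
    resp = resp, ecg = ecg,
    resp_scaled = resp_scaled, ecg_scaled = ecg_scaled,
    resp_result = resp_result, ecg_result = ecg_result,
    cr_ttl = cr_ttl, schedule = schedule, magnetization = record,
    stability = stability, latency = latency, summary = summary,
    config = config
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(output_dir, f)
    write_trace_csv(resp$trace, p("raw_resp.csv"))
    write_trace_csv(ecg$trace, p("raw_ecg.csv"))
    write_trace_csv(resp_scaled, p("scaled_resp.csv"))
    write_trace_csv(ecg_scaled, p("scaled_ecg.csv"))
    write_ground_truth_json(resp$truth, p("resp_truth.json"))
    write_ground_truth_json(ecg$truth, p("ecg_truth.json"))
    write_ttl_json(resp_result$threshold_ttl, p("resp_threshold_ttl.json"))
    write_ttl_json(resp_result$acquire_ttl, p("resp_acquire_ttl.json"))
    write_ttl_json(ecg_result$ecg_ttl, p("ecg_ttl.json"))
    write_ttl_json(cr_ttl, p("cr_ttl.json"))
    write_schedule_jsonl(schedule, p("schedule.jsonl"))
    write_magnetization_csv(record, p("magnetization.csv"))
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  out
}

#' Export the nine-channel signal pathway as one CSV
#'
#' Writes the complete gate signal pathway - raw and scaled respiration, the
#' respiratory threshold and acquire gate lines, raw and scaled ECG, the ECG
#' difference, the cardiac TTL and the combined cardio-respiratory TTL - as
#' aligned columns sampled on a common grid, for audit plots of the whole
#' processing chain.
#'
#' @param pipeline A result of [run_pipeline()].
#' @param path File path.
#' @param sample_interval Output sampling grid, ms.
#' @return `path`, invisibly.
#' @export
export_trace_bundle <- function(pipeline, path, sample_interval = 1) {
  t_end <- min(trace_end(pipeline$resp$trace), trace_end(pipeline$ecg$trace))
  times <- seq(0, t_end, by = sample_interval)
  at <- function(trace) {
    idx <- pmin(length(trace$values),
                pmax(1, round((times - trace$start_time) / trace$sample_interval) + 1))
    trace$values[idx]
  }
  lvl <- function(ttl) ifelse(ttl_is_high(ttl, times), 5, 0)
  df <- data.frame(
    time_ms = times,
    raw_resp = at(pipeline$resp$trace),
    scaled_resp = at(pipeline$resp_scaled),
    resp_thresh_ttl = lvl(pipeline$resp_result$threshold_ttl),
    resp_gate_ttl = lvl(pipeline$resp_result$acquire_ttl),
    raw_ecg = at(pipeline$ecg$trace),
    scaled_ecg = at(pipeline$ecg_scaled),
    ecg_diff = at(pipeline$ecg_result$difference_trace),
    ecg_ttl = lvl(pipeline$ecg_result$ecg_ttl),
    cr_ttl = lvl(pipeline$cr_ttl)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Animal changeover table
#'
#' Session log of a high-throughput imaging workflow: one row per scan with
#' the animal identifier, repeat number, the scan start time relative to the
#' previous scan start (minutes; 0 for the first scan of the session) and
#' the scan identifier. The duration of the final scan closes the total
#' session span.
#'
#' @param rows Data frame with columns `animal_id`, `repeat_no`,
#'   `relative_start_min`, `scan_id`.
#' @param final_scan_duration Duration of the last scan, minutes.
#' @return An object of class `changeover_table`.
#' @export
changeover_table <- function(rows, final_scan_duration) {
  need <- c("animal_id", "repeat_no", "relative_start_min", "scan_id")
  if (!is.data.frame(rows) || !all(need %in% names(rows)) || nrow(rows) < 1) {
    stop("rows must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(rows$relative_start_min[-1] <= 0)) {
    stop("relative_start_min must be positive for all rows after the first",
         call. = FALSE)
  }
  stopifnot_scalar(final_scan_duration, "final_scan_duration", positive = TRUE)
  structure(list(rows = rows, final_scan_duration = final_scan_duration),
            class = "changeover_table")
}

#' Read a changeover table from CSV
#'
#' Expects columns `animal_id`, `repeat_no`, `relative_start_min`,
#' `scan_duration_min` (may be empty except for the final scan), `scan_id`.
#' The packaged example session is at
#' `system.file("extdata", "animal_changeovers.csv", package = "cinegate")`.
#'
#' @param path CSV file path.
#' @return A [changeover_table()].
#' @export
read_changeover_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  final_dur <- df$scan_duration_min[nrow(df)]
  if (is.na(final_dur)) {
    stop("the final row must carry scan_duration_min", call. = FALSE)
  }
  changeover_table(df[, c("animal_id", "repeat_no", "relative_start_min", "scan_id")],
                   final_scan_duration = final_dur)
}

#' Throughput report from a changeover table
#'
#' Mean animal changeover time (mean of the between-scan start intervals),
#' the total session span (sum of the intervals plus the final scan's
#' duration) and the implied throughput in animals per hour.
#'
#' @param table A [changeover_table()].
#' @return A list: `mean_changeover_min`, `n_changes`, `total_span_min`,
#'   `mice_per_hour`.
#' @export
throughput_report <- function(table) {
  stopifnot(inherits(table, "changeover_table"))
  intervals <- table$rows$relative_start_min[table$rows$relative_start_min > 0]
  if (length(intervals) == 0) {
    stop("no changeover intervals in the table", call. = FALSE)
  }
  mean_ch <- mean(intervals)
  list(
    mean_changeover_min = mean_ch,
    n_changes = length(intervals),
    total_span_min = sum(table$rows$relative_start_min) + table$final_scan_duration,
    mice_per_hour = 60 / mean_ch
  )
}
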