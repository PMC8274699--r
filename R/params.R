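#' Physiological simulator parameters
#'
#' Collects every dial of the synthetic ECG / respiration generator. Defaults
#' emulate an anaesthetised mouse as monitored on a preclinical scanner:
#' respiration period 1000 (+/- 100) ms, cardiac period 134 (+/- 10) ms,
#' a 2.5 ms-wide R-wave, and gradient-switching pickup of up to 20% of the
#' R-wave peak-to-peak voltage. Periods are drawn independently and uniformly
#' from `mean +/- span` per cycle.
#'
#' @param resp_period_mean,resp_period_span Respiration period mean and
#'   half-width of its uniform jitter, ms.
#' @param cardiac_period_mean,cardiac_period_span Cardiac (R-R) period mean and
#'   jitter half-width, ms.
#' @param r_wave_width Full width at half maximum of the R-wave peak, ms
#'   (the true, pre-amplifier width).
#' @param r_wave_amplitude R-wave peak amplitude, volts (raw, +/-10 V domain).
#' @param breath_pulse_width Duration of one breath pulse, ms.
#' @param breath_amplitude Breath pulse amplitude, volts.
#' @param baseline_drift_amplitude,baseline_drift_period Amplitude (volts) and
#'   period (ms) of the slow sinusoidal baseline drift under the respiration
#'   signal.
#' @param gradient_noise_fraction Gradient-burst noise peak-to-peak amplitude
#'   as a fraction of the R-wave peak-to-peak voltage, in `[0, 1]`.
#' @param resp_coupling_gain Dimensionless gain with which the respiration
#'   waveform couples additively into the ECG channel (the slow voltage the
#'   ECG difference filter must remove). Set to 0 to disable.
#' @param sample_rate Master sampling rate, samples per second. The simulator
#'   works at the detector's fastest rate (10 kHz) so that slower channels can
#'   be derived by decimation without resampling artefacts.
#' @return An object of class `physio_params`.
#' @export
physio_params <- function(resp_period_mean = 1000,
                          resp_period_span = 100,
                          cardiac_period_mean = 134,
                          cardiac_period_span = 10,
                          r_wave_width = 2.5,
                          r_wave_amplitude = 6,
                          breath_pulse_width = 150,
                          breath_amplitude = 2,
                          baseline_drift_amplitude = 0.2,
                          baseline_drift_period = 30000,
                          gradient_noise_fraction = 0.2,
                          resp_coupling_gain = 0.05,
                          sample_rate = 10000) {
  stopifnot_scalar(resp_period_mean, "resp_period_mean", positive = TRUE)
  stopifnot_scalar(resp_period_span, "resp_period_span", nonneg = TRUE)
  stopifnot_scalar(cardiac_period_mean, "cardiac_period_mean", positive = TRUE)
  stopifnot_scalar(cardiac_period_span, "cardiac_period_span", nonneg = TRUE)
  stopifnot_scalar(r_wave_width, "r_wave_width", positive = TRUE)
  stopifnot_scalar(r_wave_amplitude, "r_wave_amplitude", positive = TRUE)
  stopifnot_scalar(breath_pulse_width, "breath_pulse_width", positive = TRUE)
  stopifnot_scalar(breath_amplitude, "breath_amplitude", positive = TRUE)
  stopifnot_scalar(baseline_drift_amplitude, "baseline_drift_amplitude", nonneg = TRUE)
  stopifnot_scalar(baseline_drift_period, "baseline_drift_period", positive = TRUE)
  stopifnot_scalar(gradient_noise_fraction, "gradient_noise_fraction", nonneg = TRUE)
  stopifnot_scalar(resp_coupling_gain, "resp_coupling_gain", nonneg = TRUE)
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (resp_period_span >= resp_period_mean) {
    stop("resp_period_span must be smaller than resp_period_mean", call. = FALSE)
  }
  if (cardiac_period_span >= cardiac_period_mean) {
    stop("cardiac_period_span must be smaller than cardiac_period_mean", call. = FALSE)
  }
  if (gradient_noise_fraction > 1) {
    stop("gradient_noise_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (breath_pulse_width >= resp_period_mean - resp_period_span) {
    stop("breath_pulse_width must be shorter than the shortest respiration period (breaths would overlap)",
         call. = FALSE)
  }
  structure(list(
    resp_period_mean = resp_period_mean,
    resp_period_span = resp_period_span,
    cardiac_period_mean = cardiac_period_mean,
    cardiac_period_span = cardiac_period_span,
    r_wave_width = r_wave_width,
    r_wave_amplitude = r_wave_amplitude,
    breath_pulse_width = breath_pulse_width,
    breath_amplitude = breath_amplitude,
    baseline_drift_amplitude = baseline_drift_amplitude,
    baseline_drift_period = baseline_drift_period,
    gradient_noise_fraction = gradient_noise_fraction,
    resp_coupling_gain = resp_coupling_gain,
    sample_rate = sample_rate
  ), class = "physio_params")
}

#' Amplifier front-end model
#'
#' Emulates the physiological signal amplifier as a pure propagation delay
#' plus a normalized moving-average that broadens sharp peaks, matching the
#' two published facts about the hardware chain: the ECG audio-filters delay
#' the signal by 4 ms and broaden a 2-3 ms R-wave to about 7 ms; the
#' respiration channel's 10 Hz low-pass delays by more than 50 ms.
#'
#' @param propagation_delay Signal propagation delay, ms.
#' @param smoothing_width Moving-average window width, ms (0 = no smoothing).
#' @param channel `"ecg"` or `"resp"`; only a label.
#' @param slew_rate_limit Optional maximum |dV/dt| in volts/ms applied after
#'   smoothing (the hardware has a slew-rate limiter whose parameters are
#'   unpublished); `Inf` disables it.
#' @return An object of class `amplifier_model`.
#' @export
amplifier_model <- function(propagation_delay = 4,
                            smoothing_width = 4.5,
                            channel = c("ecg", "resp"),
                            slew_rate_limit = Inf) {
  channel <- match.arg(channel)
  stopifnot_scalar(propagation_delay, "propagation_delay", nonneg = TRUE)
  stopifnot_scalar(smoothing_width, "smoothing_width", nonneg = TRUE)
  if (!identical(slew_rate_limit, Inf)) {
    stopifnot_scalar(slew_rate_limit, "slew_rate_limit", positive = TRUE)
  }
  structure(list(
    propagation_delay = propagation_delay,
    smoothing_width = smoothing_width,
    channel = channel,
    slew_rate_limit = slew_rate_limit
  ), class = "amplifier_model")
}

#' Default respiration amplifier
#'
#' The respiration channel's 10 Hz low-pass filter invokes a delay in excess
#' of 50 ms; 55 ms delay with a 50 ms smoothing window is used as the default
#' emulation. The delay is deliberately not compensated anywhere in the gate
#' path: breaths are detected late and the damage is repaired by k-space block
#' re-acquisition, as in the hardware.
#'
#' @return An `amplifier_model` for the respiration channel.
#' @export
resp_amplifier_model <- function() {
  amplifier_model(propagation_delay = 55, smoothing_width = 50, channel = "resp")
}

#' Voltage scaling board configuration
#'
#' Affine conditioning of the +/-10 V amplifier outputs onto the 0 to +5 V
#' input range of the gate microprocessors, with user gain and DC offset and
#' hard saturation at the output rails (the board clips, it does not fail).
#'
#' @param input_min,input_max Input range, volts.
#' @param output_min,output_max Output range, volts.
#' @param gain Dimensionless gain applied after the affine map.
#' @param dc_offset Offset, volts, applied after the gain.
#' @return An object of class `scaler_config`.
#' @export
scaler_config <- function(input_min = -10, input_max = 10,
                          output_min = 0, output_max = 5,
                          gain = 1, dc_offset = 0) {
  stopifnot_scalar(input_min, "input_min")
  stopifnot_scalar(input_max, "input_max")
  stopifnot_scalar(output_min, "output_min")
  stopifnot_scalar(output_max, "output_max")
  stopifnot_scalar(gain, "gain")
  stopifnot_scalar(dc_offset, "dc_offset")
  if (input_max <= input_min) stop("input_max must exceed input_min", call. = FALSE)
  if (output_max <= output_min) stop("output_max must exceed output_min", call. = FALSE)
  structure(list(
    input_min = input_min, input_max = input_max,
    output_min = output_min, output_max = output_max,
    gain = gain, dc_offset = dc_offset
  ), class = "scaler_config")
}

#' Respiratory gate configuration
#'
#' Dials of the respiration gating microprocessor: the 10 ms digitisation
#' grid, the detection threshold on the 2-point differential (or, in slope
#' mode, on the per-millisecond slope of the scaled signal), the
#' trailing-edge termination fraction (pulse ends when the monitored signal
#' falls through onset + fraction * (max - onset); default 20%), and the
#' user dial that extends the no-acquire window past the detected breath end.
#'
#' @param sample_interval Digitisation interval, ms.
#' @param threshold Detection threshold, volts (differential mode) or
#'   volts/ms (slope mode).
#' @param trailing_fraction Termination level as a fraction of the excursion
#'   between onset and pulse maximum, in (0, 1).
#' @param no_acquire_extension Extension of the no-acquire window beyond the
#'   threshold pulse, ms.
#' @param acquire_max_duration Optional manual shortening of each acquire
#'   window, ms (`Inf` = acquire until the next breath).
#' @param termination_timeout Force-termination of a threshold pulse whose
#'   trailing edge never crosses the termination level, ms.
#' @param mode `"differential"` (threshold on the 2-point differential) or
#'   `"slope"` (threshold on the leading-edge slope, termination on the raw
#'   scaled voltage).
#' @return An object of class `resp_gate_config`.
#' @export
resp_gate_config <- function(sample_interval = 10,
                             threshold = 0.05,
                             trailing_fraction = 0.20,
                             no_acquire_extension = 150,
                             acquire_max_duration = Inf,
                             termination_timeout = 400,
                             mode = c("differential", "slope")) {
  mode <- match.arg(mode)
  stopifnot_scalar(sample_interval, "sample_interval", positive = TRUE)
  stopifnot_scalar(threshold, "threshold", positive = TRUE)
  stopifnot_scalar(trailing_fraction, "trailing_fraction", positive = TRUE)
  stopifnot_scalar(no_acquire_extension, "no_acquire_extension", nonneg = TRUE)
  if (!identical(acquire_max_duration, Inf)) {
    stopifnot_scalar(acquire_max_duration, "acquire_max_duration", positive = TRUE)
  }
  stopifnot_scalar(termination_timeout, "termination_timeout", positive = TRUE)
  if (trailing_fraction >= 1) {
    stop("trailing_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    sample_interval = sample_interval,
    threshold = threshold,
    trailing_fraction = trailing_fraction,
    no_acquire_extension = no_acquire_extension,
    acquire_max_duration = acquire_max_duration,
    termination_timeout = termination_timeout,
    mode = mode
  ), class = "resp_gate_config")
}

#' Cardiac (ECG) gate configuration
#'
#' Dials of the two-rate R-wave detector: 1 kHz baseline digitisation with a
#' 2-point difference over a 4 ms lag (the lag equals one TR so that
#' TR-periodic gradient pickup cancels in the difference), an arming threshold
#' on that difference, a 10 kHz burst-sampling rate for turning-point peak
#' localisation, and the operator-set TTL pulse duration. The TTL duration
#' must exceed one TR and be shorter than one CINE block; during the TTL the
#' detector will not re-arm (refractory).
#'
#' @param base_sample_interval Baseline digitisation interval, ms.
#' @param diff_lag Difference lag, ms; must be a positive multiple of
#'   `base_sample_interval`.
#' @param arm_threshold Arming threshold on the difference signal, volts.
#' @param fast_sample_interval Fast (peak-search) sampling interval, ms.
#' @param ttl_duration Cardiac TTL pulse duration, ms.
#' @param refractory Re-arming dead time from TTL onset, ms; defaults to
#'   `ttl_duration`.
#' @param arm_timeout Maximum time to spend in fast sampling without finding a
#'   turning point before disarming, ms (noise-burst safeguard).
#' @return An object of class `ecg_gate_config`.
#' @export
ecg_gate_config <- function(base_sample_interval = 1,
                            diff_lag = 4,
                            arm_threshold = 0.3,
                            fast_sample_interval = 0.1,
                            ttl_duration = 16,
                            refractory = NULL,
                            arm_timeout = 20) {
  stopifnot_scalar(base_sample_interval, "base_sample_interval", positive = TRUE)
  stopifnot_scalar(diff_lag, "diff_lag", positive = TRUE)
  stopifnot_scalar(arm_threshold, "arm_threshold", positive = TRUE)
  stopifnot_scalar(fast_sample_interval, "fast_sample_interval", positive = TRUE)
  stopifnot_scalar(ttl_duration, "ttl_duration", positive = TRUE)
  if (is.null(refractory)) refractory <- ttl_duration
  stopifnot_scalar(refractory, "refractory", nonneg = TRUE)
  stopifnot_scalar(arm_timeout, "arm_timeout", positive = TRUE)
  if (fast_sample_interval >= base_sample_interval) {
    stop("fast_sample_interval must be smaller than base_sample_interval", call. = FALSE)
  }
  k <- diff_lag / base_sample_interval
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("diff_lag must be a positive multiple of base_sample_interval", call. = FALSE)
  }
  structure(list(
    base_sample_interval = base_sample_interval,
    diff_lag = diff_lag,
    arm_threshold = arm_threshold,
    fast_sample_interval = fast_sample_interval,
    ttl_duration = ttl_duration,
    refractory = refractory,
    arm_timeout = arm_timeout
  ), class = "ecg_gate_config")
}

#' Scan (pulse-sequence) parameters
#'
#' Parameters of the gated CINE acquisition: constant TR, number of CINE
#' frames per block, number of phase-encode lines, the count of consecutive
#' gate-evaluation loop operations beyond which a breath (or missed R-wave)
#' is declared, and the number of preceding CINE blocks re-acquired after a
#' declared breath. Defaults give a 4 ms TR, an 80 ms CINE envelope, and a
#' 100 ms breath-declaration latency (strict "more than 25" ticks of 4 ms).
#'
#' @param tr Repetition time, ms.
#' @param n_frames CINE frames per block (NE).
#' @param n_phase_encodes Number of phase-encode lines.
#' @param breath_count_threshold A breath is declared when the consecutive
#'   gate-evaluation tick count exceeds this value (strict inequality).
#' @param n_reacquire Number of preceding blocks re-acquired per declared
#'   breath.
#' @param mode Gating scheme: `"tssm"` (true steady-state maintenance,
#'   constant TR throughout), `"ccrt"` (conventional cardio-respiratory
#'   triggering, RF suspended between blocks and during breaths) or `"dg"`
#'   (double gating, RF after every heartbeat, data kept only outside
#'   breaths).
#' @param localiser_segments Phase encodes per R-wave in localiser mode
#'   (centre-out ordering).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(tr = 4,
                        n_frames = 20,
                        n_phase_encodes = 128,
                        breath_count_threshold = 25,
                        n_reacquire = 2,
                        mode = c("tssm", "ccrt", "dg"),
                        localiser_segments = 4) {
  mode <- match.arg(mode)
  stopifnot_scalar(tr, "tr", positive = TRUE)
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  stopifnot_scalar(n_phase_encodes, "n_phase_encodes", positive = TRUE)
  stopifnot_scalar(breath_count_threshold, "breath_count_threshold", positive = TRUE)
  stopifnot_scalar(n_reacquire, "n_reacquire", nonneg = TRUE)
  stopifnot_scalar(localiser_segments, "localiser_segments", positive = TRUE)
  structure(list(
    tr = tr,
    n_frames = as.integer(n_frames),
    n_phase_encodes = as.integer(n_phase_encodes),
    breath_count_threshold = as.integer(breath_count_threshold),
    n_reacquire = as.integer(n_reacquire),
    mode = mode,
    localiser_segments = as.integer(localiser_segments)
  ), class = "scan_params")
}

#' Tissue relaxation parameters
#'
#' @param m0 Equilibrium longitudinal magnetization, arbitrary units.
#' @param t1 Longitudinal relaxation time, ms. The default 1500 ms is a
#'   muscle-like placeholder at 7 T.
#' @param t2_star Effective transverse relaxation time, ms.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(m0 = 1, t1 = 1500, t2_star = 20) {
  stopifnot_scalar(m0, "m0", positive = TRUE)
  stopifnot_scalar(t1, "t1", positive = TRUE)
  stopifnot_scalar(t2_star, "t2_star", positive = TRUE)
  structure(list(m0 = m0, t1 = t1, t2_star = t2_star), class = "tissue_params")
}

#' Sequence (contrast) parameters
#'
#' @param flip_angle Excitation flip angle, degrees, in (0, 90].
#' @param te Echo time, ms; must be shorter than `tr`.
#' @param tr Repetition time, ms (must match the scan parameters when used
#'   together).
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(flip_angle = 15, te = 1.89, tr = 4) {
  stopifnot_scalar(flip_angle, "flip_angle", positive = TRUE)
  stopifnot_scalar(te, "te", positive = TRUE)
  stopifnot_scalar(tr, "tr", positive = TRUE)
  if (flip_angle > 90) stop("flip_angle must lie in (0, 90] degrees", call. = FALSE)
  if (te >= tr) stop("te must be shorter than tr", call. = FALSE)
  structure(list(flip_angle = flip_angle, te = te, tr = tr),
            class = "sequence_params")
}
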