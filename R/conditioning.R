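#' Apply the amplifier model to a trace
#'
#' Delays the trace by `propagation_delay` (rounded to the sampling grid) and
#' convolves it with a normalized moving average of width `smoothing_width`,
#' broadening sharp peaks while preserving the DC level. Edge samples are
#' padded with the first/last value. An optional slew-rate limit clamps the
#' per-sample voltage change.
#'
#' The operator is linear: `amp(a*x + b*y) = a*amp(x) + b*amp(y)` (away from
#' an active slew-rate limiter, which is off by default).
#'
#' @param trace A [waveform_trace()].
#' @param model An [amplifier_model()].
#' @return A [waveform_trace()] with the same grid.
#' @export
apply_amplifier <- function(trace, model) {
  stopifnot(inherits(trace, "waveform_trace"), inherits(model, "amplifier_model"))
  dt <- trace$sample_interval
  if (model$smoothing_width >= trace_duration(trace)) {
    stop("smoothing_width must be shorter than the trace", call. = FALSE)
  }
  v <- trace$values
  n <- length(v)
  # moving average over an odd number of samples so a symmetric peak stays put
  w <- as.integer(round(model$smoothing_width / dt))
  if (w >= 2L) {
    if (w %% 2L == 0L) w <- w + 1L
    half <- (w - 1L) %/% 2L
    padded <- c(rep(v[1], half), v, rep(v[n], half))
    kern <- rep(1 / w, w)
    v <- as.numeric(stats::filter(padded, kern, sides = 2))[(half + 1):(half + n)]
  }
  shift <- as.integer(round(model$propagation_delay / dt))
  if (shift > 0L) {
    v <- c(rep(v[1], min(shift, n)), v)[seq_len(n)]
  }
  if (is.finite(model$slew_rate_limit)) {
    max_step <- model$slew_rate_limit * dt
    for (i in 2:n) {
      d <- v[i] - v[i - 1]
      if (d > max_step) v[i] <- v[i - 1] + max_step
      else if (d < -max_step) v[i] <- v[i - 1] - max_step
    }
  }
  out <- trace
  out$values <- v
  out$channel_label <- paste0(trace$channel_label, "_amp")
  out
}

#' Voltage-scale a trace onto the gate input range
#'
#' Affine map of `[input_min, input_max]` onto `[output_min, output_max]`,
#' followed by the user gain and DC offset, then hard clipping to the output
#' rails. Clipping mirrors the saturation of the hardware scaling board; the
#' number of clipped samples is attached as attribute `"clip_count"` and a
#' warning is raised when it is non-zero.
#'
#' With unit gain and zero offset the map is invertible on in-range inputs.
#'
#' @param trace A [waveform_trace()].
#' @param cfg A [scaler_config()].
#' @return A [waveform_trace()] in the output voltage domain, with attribute
#'   `clip_count`.
#' @export
scale_voltage <- function(trace, cfg = scaler_config()) {
  stopifnot(inherits(trace, "waveform_trace"), inherits(cfg, "scaler_config"))
  span_in <- cfg$input_max - cfg$input_min
  span_out <- cfg$output_max - cfg$output_min
  v <- (trace$values - cfg$input_min) / span_in * span_out + cfg$output_min
  v <- cfg$gain * v + cfg$dc_offset
  clipped <- v < cfg$output_min | v > cfg$output_max
  v <- pmin(pmax(v, cfg$output_min), cfg$output_max)
  if (any(clipped)) {
    warning(sprintf("scale_voltage: %d sample(s) clipped at the output rails",
                    sum(clipped)), call. = FALSE)
  }
  out <- trace
  out$values <- v
  out$channel_label <- paste0(sub("_amp$", "", trace$channel_label), "_scaled")
  attr(out, "clip_count") <- sum(clipped)
  out
}
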