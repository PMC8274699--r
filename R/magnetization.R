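#' Closed-form spoiled gradient-echo steady state
#'
#' Longitudinal magnetization just before each pulse under constant-TR
#' pulsing converges to `M0 (1 - E1) / (1 - E1 cos(alpha))` with
#' `E1 = exp(-TR/T1)`.
#'
#' @param tissue A [tissue_params()].
#' @param seq_par A [sequence_params()].
#' @return Steady-state `Mz` before the pulse, arbitrary units.
#' @export
flash_steady_state <- function(tissue, seq_par) {
  e1 <- exp(-seq_par$tr / tissue$t1)
  a <- seq_par$flip_angle * pi / 180
  tissue$m0 * (1 - e1) / (1 - e1 * cos(a))
}

#' Evolve longitudinal magnetization through an RF schedule
#'
#' Piecewise relaxation/excitation model with perfect spoiling (no
#' transverse coherence survives a TR): between pulses
#' `Mz(t + d) = M0 + (Mz(t) - M0) exp(-d/T1)`; each pulse tips `Mz` by the
#' flip angle, leaving `Mz cos(alpha)` and emitting a signal
#' `Mz sin(alpha) exp(-TE/T2*)`. The starting magnetization is `M0`. Pulses
#' that coincide with a CINE frame of a data-carrying block are labelled with
#' the block row and frame index so that per-frame intensity series can be
#' extracted.
#'
#' @param schedule An `acquisition_schedule` (its `rf_pulse_times` drive the
#'   evolution).
#' @param tissue A [tissue_params()].
#' @param seq_par A [sequence_params()]; its `tr` should match the scan's.
#' @return An object of class `magnetization_record`: a data frame-backed
#'   record with `pulse_times`, `mz_before`, `signal`, `block` (row in
#'   `schedule$blocks` or `NA`), `frame` (0-based frame index or `NA`) and
#'   `status` of the owning block.
#' @export
evolve_magnetization <- function(schedule, tissue, seq_par = sequence_params()) {
  stopifnot(inherits(schedule, "acquisition_schedule"),
            inherits(tissue, "tissue_params"),
            inherits(seq_par, "sequence_params"))
  pulses <- schedule$rf_pulse_times
  if (length(pulses) == 0) {
    return(structure(list(
      pulse_times = numeric(0), mz_before = numeric(0), signal = numeric(0),
      block = integer(0), frame = integer(0), status = character(0),
      tissue = tissue, seq_par = seq_par
    ), class = "magnetization_record"))
  }
  a <- seq_par$flip_angle * pi / 180
  echo <- exp(-seq_par$te / tissue$t2_star)
  m0 <- tissue$m0
  t1 <- tissue$t1
  n <- length(pulses)
  mz <- numeric(n)
  m <- m0
  prev_t <- pulses[1]
  for (i in seq_len(n)) {
    gap <- pulses[i] - prev_t
    if (gap > 0) m <- m0 + (m - m0) * exp(-gap / t1)
    mz[i] <- m
    m <- m * cos(a)
    prev_t <- pulses[i]
  }
  signal <- mz * sin(a) * echo

  # label pulses that are CINE frames of each block
  ne <- schedule$params$n_frames
  tr <- schedule$params$tr
  block <- rep(NA_integer_, n)
  frame <- rep(NA_integer_, n)
  status <- rep(NA_character_, n)
  if (nrow(schedule$blocks) > 0) {
    key <- round(pulses / tr * 4)     # robust grid key
    lut <- new.env(hash = TRUE, size = n)
    for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lut)
    for (b in seq_len(nrow(schedule$blocks))) {
      ft <- schedule$blocks$start_time[b] + (0:(ne - 1)) * tr
      fk <- as.character(round(ft / tr * 4))
      for (f in seq_len(ne)) {
        i <- lut[[fk[f]]]
        if (!is.null(i)) {
          block[i] <- b
          frame[i] <- f - 1L
          status[i] <- schedule$blocks$status[b]
        }
      }
    }
  }
  structure(list(
    pulse_times = pulses, mz_before = mz, signal = signal,
    block = block, frame = frame, status = status,
    tissue = tissue, seq_par = seq_par
  ), class = "magnetization_record")
}

#' @export
print.magnetization_record <- function(x, ...) {
  cat(sprintf(
    "<magnetization_record> %d RF pulse(s), %d frame-labelled, Mz range [%.4g, %.4g]\n",
    length(x$pulse_times), sum(!is.na(x$frame)),
    if (length(x$mz_before)) min(x$mz_before) else NA,
    if (length(x$mz_before)) max(x$mz_before) else NA
  ))
  invisible(x)
}

#' @export
as.data.frame.magnetization_record <- function(x, ...) {
  data.frame(
    time_ms = x$pulse_times, mz_before = x$mz_before, signal = x$signal,
    block_index = x$block, frame_index = x$frame, status = x$status
  )
}

#' Write the per-pulse signal series as CSV
#'
#' @param record A `magnetization_record`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_magnetization_csv <- function(record, path) {
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}

#' Signal-stability metrics across frames and repeats
#'
#' Coefficient-of-variation summaries of the kept-frame signal amplitudes,
#' after discarding a burn-in period during which the steady state is still
#' forming. `short_term_cv` is the CV across the CINE frame dimension (of the
#' per-frame-index mean signal); `long_term_cv` is the CV of the first-frame
#' signal across repeats when a list of records (a repeated dynamic series)
#' is supplied, and across blocks within the single record otherwise.
#'
#' @param records A `magnetization_record` or a list of them.
#' @param burn_in Time (ms) from the start of each record to exclude.
#' @return A list with `short_term_cv` and `long_term_cv`.
#' @export
stability_metrics <- function(records, burn_in = 5000) {
  if (inherits(records, "magnetization_record")) records <- list(records)
  stopifnot(length(records) >= 1)
  cv <- function(x) stats::sd(x) / mean(x)
  frame_profiles <- list()
  first_frame_means <- numeric(0)
  within_first <- numeric(0)
  for (r in records) {
    keep <- !is.na(r$frame) & r$status == "kept" &
      r$pulse_times >= r$pulse_times[1] + burn_in
    if (!any(keep)) {
      stop("no kept frames after burn-in; shorten burn_in or lengthen the scan",
           call. = FALSE)
    }
    sig <- r$signal[keep]
    if (all(sig == 0) || mean(sig) == 0) {
      stop("zero-mean signals: CV undefined", call. = FALSE)
    }
    fr <- r$frame[keep]
    frame_profiles[[length(frame_profiles) + 1L]] <-
      tapply(sig, fr, mean)
    first_frame_means <- c(first_frame_means, mean(sig[fr == 0]))
    within_first <- c(within_first, sig[fr == 0])
  }
  profile <- Reduce(`+`, frame_profiles) / length(frame_profiles)
  long_cv <- if (length(records) >= 2) {
    cv(first_frame_means)
  } else if (length(within_first) >= 2) {
    cv(within_first)
  } else {
    NA_real_
  }
  list(short_term_cv = cv(profile), long_term_cv = long_cv)
}
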