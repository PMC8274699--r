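---
title: "Models and design of the gating simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the gating simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinegate)
```

`cinegate` emulates, in software, a hardware gating control unit for
small-animal MRI together with the prospectively gated, steady-state
maintained CINE acquisition it drives. This vignette records the models the
package implements, the dials they expose, the numerical choices made where
the hardware behaviour is under-documented, and what the simulation does and
does not claim about real data.

## The synthetic physiology

`simulate_cardiac()` and `simulate_respiration()` generate voltage traces at
a 10 kHz master rate - the fastest rate at which the gate hardware ever
digitises - so every slower channel (1 kHz ECG baseline, 100 Hz respiration
gate) is obtained by decimation rather than resampling.

Event timing is the part of the physiology that is pinned down: successive
R-R intervals are drawn independently and uniformly from 134 ± 10 ms, and
breath periods from 1000 ± 100 ms (mouse under isoflurane, 40-60
breaths/min). The uniform "mean ± span" model is deliberate: it is how the
hardware's own built-in simulator describes its variability, and the spans
are half-widths, not standard deviations.

Waveform *shape*, by contrast, is a modelling choice, because only two facts
about it are published: the true R-wave width is about 2-3 ms, and the
amplifier chain broadens it to about 7 ms while delaying its peak by 4 ms.
We use:

- **R-wave**: a Gaussian of FWHM `r_wave_width` (default 2.5 ms) flanked by
  two negative side lobes of a quarter the amplitude - the narrow positive
  spike with opposite-sign lobes of a surface-electrode QRS. Amplitude
  defaults to 6 V in the raw ±10 V domain (signals are gain-adjusted per
  animal to fill that range).
- **Breath**: a unipolar raised-cosine pulse of width `breath_pulse_width`
  (default 150 ms - a realistic inspiration duration for an anaesthetised
  mouse; the period, not the pulse width, is what the hardware documentation
  fixes) riding on a slow sinusoidal baseline drift (default 0.2 V over
  30 s). A piezo respiration transducer produces exactly this kind of
  pulse-per-breath signal.
- **Respiration-to-ECG coupling**: a small additive copy of the respiration
  waveform (gain 0.05) in the ECG channel, so that the ECG difference filter
  has a realistic slow nuisance signal to remove.

`add_gradient_noise()` models pickup from the switched imaging gradients as
a zero-mean oscillatory burst repeating every TR, with peak-to-peak
amplitude expressed as a fraction of the R-wave peak-to-peak voltage
(default 0.2, the worst case reported for surface pads). The burst waveform
is *identical from period to period*, because the gradient waveforms
themselves repeat exactly every TR. This is not an incidental choice: it is
the physical reason a 2-point ECG difference over a lag of exactly one TR
cancels gradient noise, which is why that lag was chosen empirically in the
hardware. The seed randomises only the phase of the burst train (snapped to
the sampling grid so the burst extrema are represented exactly); an optional
`amplitude_jitter` breaks the periodicity for stress testing.

## The analogue front end

`apply_amplifier()` reduces the proprietary amplifier filters to the two
published facts: a pure propagation delay (4 ms ECG; 55 ms is used for the
respiration channel's ">50 ms") plus a normalized moving average. The ECG
smoothing width of 4.5 ms makes a 2.5 ms triangular test peak come out 7 ms
wide at base, matching the published broadening. The moving average uses an
odd sample count so symmetric peaks are not shifted, and edge samples are
padded with the boundary value so the DC level is preserved. A slew-rate
limiter exists in the hardware but its parameters are unpublished, so it is
modelled as an optional max-|dV/dt| clamp, off by default.

`scale_voltage()` maps ±10 V onto the 0-5 V microprocessor input range,
applies user gain and DC offset, and then *clips* at the rails rather than
erroring - the board saturates, it does not fail. Clipped samples are
counted and reported as a warning.

## The respiratory gate

The gate digitises the scaled signal every 10 ms and differences adjacent
samples - a high-pass that removes baseline drift (a 30 s, 1 V drift leaves
at most ~2.1 mV in the differential). Detection then runs a
sample-and-compare state machine on that 10 ms grid, exactly as the
microprocessor does; no sub-sample interpolation is used anywhere, and the
first sample at or above threshold supplies the "onset voltage" (the
hardware has no access to the exact crossing instant either).

A threshold pulse terminates when the monitored signal falls through
`onset + trailing_fraction × (max − onset)` with `trailing_fraction = 0.20`.
Terminating on a fraction of the excursion rather than on the onset level
matters: breath profiles are asymmetric and the baseline is often not
reached between breaths, which would otherwise produce artificial,
apparently endless breaths. For the pathological case where even that level
is never crossed, a force-termination timeout (default 400 ms, about twice a
breath) ends the pulse and the event is counted and reported.

The no-acquire window extends the threshold pulse by `no_acquire_extension`
(default 150 ms; this is a user dial in the hardware) so that the trailing
end of the breath is covered; acquire windows fill the gaps, are optionally
shortened by `acquire_max_duration`, and always end at the next breath
detection. Acquire and no-acquire windows tile the monitored timeline by
construction - time cut off a shortened acquire window reverts to the
no-acquire line.

In slope mode the pulse starts when the leading-edge slope (V/ms) exceeds
the threshold, and terminates when the *voltage* returns through 20% of the
excursion between detection and peak - the two modes monitor different
signals and the code keeps those roles explicit.

The respiration amplifier delay (>50 ms) is deliberately not compensated:
breaths are detected late, and the damage to data acquired just before
detection is repaired by block re-acquisition, exactly as in the hardware.

## The cardiac gate

`detect_r_waves()` implements the two-rate scheme: at 1 kHz, a 2-point
difference over a 4 ms lag (TR-periodic noise cancels; the slow
respiration-coupled voltage is removed); when the difference exceeds
`arm_threshold` (default 0.3 V on the scaled signal, roughly midway between
the largest noise step and the R-wave step) the detector arms and samples
the raw scaled signal at 10 kHz; the first fast sample lower than its
predecessor marks the turning point, the peak being the predecessor. Flat
tops resolve to the first plateau sample - deterministic and
hardware-plausible. Because only *comparisons* of successive samples are
used, detection timing is provably independent of amplitude and DC level.

The TTL is raised at the sample that revealed the turning point, i.e. one
fast sample (0.1 ms) after the true peak; with a 3.5 ms amplifier delay the
total true-peak-to-TTL latency stays below 4 ms. Fast sampling reverts to
the base rate at the peak (not at TTL end) - the published trace behaviour
suggests this, and the alternative would only lengthen a bookkeeping
interval. Re-arming is inhibited for `refractory` ms from TTL onset,
defaulting to the TTL duration itself (16 ms, chosen to exceed one TR of
4 ms and stay well below one 80 ms CINE block) since the hardware implies
the TTL period gates re-arming and never states a separate refractory. An
armed search that finds no turning point within `arm_timeout` (20 ms)
disarms and is counted - the safeguard against arming on a noise burst.

R-waves *during* breaths are detected normally; suppression happens only in
the Boolean AND combination (`combine_gates()`), which truncates a cardiac
pulse straddling an acquire-window edge at the edge.

## Scan control

`run_scan()` advances a scanner clock in TR ticks from the start of the
gating window and evaluates the combined gate level once per tick - the
"gate evaluation" element of the sequence loop. A high tick launches a
20-frame CINE block on consecutive ticks; RF runs on *every* tick
(steady-state maintenance), so the multiset of RF intervals is exactly
{TR}. Because the gate is only read on the TR grid, a trigger with uniform
phase starts its first frame after a delay uniform over one TR, mean
0.5 TR - the quantization the constant-TR design accepts in exchange for a
never-interrupted steady state. Sub-TR gate evaluation is out of scope here.

A breath (or missed R-wave) is declared when the consecutive
gate-evaluation tick count *strictly exceeds* `breath_count_threshold`
(default 25, i.e. on the 26th tick, 104 ms into the silence); the 2 most
recently acquired blocks are then discarded and re-queued ahead of the
remaining lines, to be re-acquired once triggers resume after the same
breath. If fewer blocks exist, only those are re-queued. Declaration fires
once per silent gap.

Two termination details are design choices the hardware description leaves
open. First, after the last phase encode is kept, gate evaluation continues
until the next trigger or the end of the monitored window: a breath
declared in that tail still re-queues the final blocks, so data acquired
just before a trailing breath are repaired rather than silently kept.
Second, re-acquired blocks keep their normal trigger alignment; nothing
distinguishes them once re-acquired.

`run_scan_ccrt()` (scanner idles between blocks and during breaths, no
re-acquisition) and `run_scan_dg()` (RF block after every heartbeat, data
kept only outside breaths, hiatus `R-R − NE·TR` between blocks) provide the
two reference schemes. A localiser ordering (`centre_out_order()`) covers
the segmented centre-out positioning mode.

## Magnetization

`evolve_magnetization()` assumes perfect spoiling - the sequence uses RF and
gradient spoiling, and no transverse history survives a TR - so longitudinal
magnetization follows the scalar recursion given in the README, and at
constant TR converges to the closed-form FLASH steady state (the two agree
to better than 1e-10 after 10·T1/TR pulses; the approach is monotone for
flip angles up to 90°).

Tissue defaults (T1 1500 ms, T2* 20 ms, muscle-like at 7 T) are exposed
placeholders: no tissue values are pinned down for the stability
comparisons, so only *ordering* and *constancy* claims are made.
`stability_metrics()` reports coefficients of variation of kept-frame
signals after a 5 s burn-in (the steady state forms with time constant
`−TR/ln(E1 cos α)` ≈ 110 ms here, so 5 s is conservative): across the CINE
frame dimension (short term) and across repeats or blocks (long term).
Under identical physiology, short-term CV orders cCRT > DG > tSSM for flip
angles of 10° and above, with tSSM's CV at numerical zero - recovery gaps
elevate the first frames of cCRT blocks above the steady state, DG's
constant hiatus does the same more mildly, and tSSM has no gaps at all.

## Problem sizes and numerical choices

The packaged tests and the acceptance script use desk-scale runs chosen to
make every Monte-Carlo comparison decisive: 10,000 triggers for the jitter
distribution (standard error of the mean ≈ 0.003 TR), 200 beats for the
noisy-latency bound, 1000 beats for R-R statistics (standard error
≈ 0.18 ms), and 20 independent 128-line scans for the per-slice duration.
Simulated recordings run at 10 kHz for 45 s at most, i.e. 450,001 samples -
small enough to keep every test deterministic and fast.

Times are milliseconds and voltages volts throughout; all event times are
absolute from trace start. Crossing detection is sample-and-compare on each
consumer's own grid; TTL intervals are half-open `[start, end)`; trace CSV
files are written at full double precision so round trips are lossless.

## What passing tests do and do not show

The generator reproduces timing statistics, amplitude scales, drift,
coupling and TR-periodic noise - the features the gating algorithms must
tolerate. It does not attempt physiologically realistic PQRST morphology,
arrhythmias, magnetohydrodynamic artefacts, amplitude variability between
beats, or multipolar respiration signals; robustness to those is exactly
what the hardware dials (thresholds, extensions, timeouts) exist for, and
claims about them are out of scope. Likewise the magnetization model stops
at per-frame signal amplitudes for a stable tissue: inflow, ghosting,
k-space effects and image reconstruction are not modelled, so simulated
stability metrics support ordering claims, not quantitative image
intensities.
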