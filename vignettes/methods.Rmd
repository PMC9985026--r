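---
title: "Methods: detecting vasoconstriction from chest PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting vasoconstriction from chest PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(vasoppg)
```

## Problem

Systemic vasoconstriction — the reflexive narrowing of peripheral blood
vessels under sympathetic activation — reduces pulsatile blood volume in
skin tissue. A chest-worn optical sensor records this as a drop in the
pulse amplitude of the photoplethysmogram (PPG). This package turns
dual-channel (red and infrared) 50 Hz PPG recordings into a per-event
**percent vasoconstriction** statistic

$$\%\,\mathrm{vaso} = 100\left(1 - \frac{E_{\min}}{B}\right)$$

where $E$ is the analytic (Hilbert) envelope of the band-passed pulse
waveform and $B$ is its 60 s running-average baseline, and segments,
sizes and reports discrete constriction events.

## Signal model and simulator

`simulate_recording()` generates ground-truthed recordings for
validation:

- a periodic pulse template (systolic Gaussian at relative phase 0.2
  plus a smaller diastolic wave at 0.35, wrapped and normalized so its
  maximum equals the programmed amplitude);
- beat-to-beat heart-period jitter (lognormal-free: per-beat periods are
  `base * (1 + jitter)` with Gaussian jitter, default 3 % SD);
- respiratory amplitude modulation (default 15 breaths/min, 10 %);
- additive white noise per channel (default 5 % of pulse amplitude);
- optional motion artifacts `(time, duration, relative amplitude)`;
- programmed constriction events (`vaso_event_spec()`): an exponential
  amplitude fall (time constant `onset_tau_s = 0.5` s, truncated at
  $7\tau$), an exact plateau at $1 - d$ for `plateau_s = 3` s, then
  exponential recovery (`recovery_tau_s = 1` s). With these defaults an
  event removes roughly 7 amplitude-seconds from the 60 s baseline
  window, so the literal (unmasked) baseline overestimates depth by
  under 1.5 percentage points at 40 % depth — the dominant term in the
  pipeline's depth-recovery error.

Both channels share one amplitude envelope; the infrared AC amplitude is
`ir_red_ratio = 1.8` times the red, reflecting deeper optical
penetration. Samples are offset by $2^{17}$ counts and quantized to an
18-bit ADC range.

```{r simulate}
sim <- simulate_recording(sim_config(
  duration_s = 240, seed = 7,
  event_schedule = list(vaso_event_spec(onset_s = 120, depth_pct = 30))))
sim$recording
```

## Signal quality: biased autocorrelation and periodicity

`biased_autocorrelation()` computes
$r(k) = \frac{1}{T}\sum_t \tilde x_t \tilde x_{t+k} \,/\, c_0$ with the
$1/T$ (biased) normalization, so $|r(k)| \le 1$ and estimates taper with
lag. `estimate_beat_period()` takes the highest autocorrelation local
maximum inside the physiological lag window (40–180 bpm); a floor of
0.15 on that maximum makes pure noise raise a "no beat" error rather
than return a spurious period. `periodicity_score()` averages the local
maxima nearest to 1–3 multiples of the beat lag and divides by $r(0)$:
near 1 for clean repetitive pulses, near 0 for noise.

Two readings of "clean" matter here. With every stochastic term disabled
(no additive noise, no respiratory modulation, *and* no heart-period
jitter) the score of a filtered simulated recording is about 0.99.
Default 3 % beat jitter alone lowers it to about 0.91, because jitter
decorrelates lags 2–3 exactly the way noise does; jitter *is* noise in
the autocorrelation sense.

```{r periodicity}
clean <- simulate_recording(sim_config(duration_s = 180, hr_jitter_pct = 0,
                                       noise_sd_frac = 0, resp_amp_frac = 0,
                                       seed = 2))$recording
f <- filter_signal(clean$ir - mean(clean$ir), design_fir(filter_spec()))
periodicity_score(as.numeric(f)[500:8500], 50)$score
```

## Filtering and envelope

`design_fir()` builds a windowed-sinc band-pass (default 0.5–10 Hz,
covering heart rates and pulse harmonics while rejecting DC drift and
high-frequency noise) tapered by a Kaiser window (`kaiser_window()`,
default $N = 500$, $\beta = 8$; `bessel_i0()` is a power series
truncated at $10^{-16}$ relative). `filter_signal()` compensates the
group delay of $\lfloor (N-1)/2 \rfloor$ samples; with even $N$ a
half-sample residual remains, which is irrelevant for envelope work.
Inputs must be demeaned first — a raw $2^{17}$-count DC offset drives a
large step response at the edges.

`analytic_envelope()` forms the analytic signal by zeroing the negative
FFT frequencies (an FIR Hilbert-transformer variant is available for
streaming-style use) and returns its magnitude. `envelope_series()`
additionally returns a 2 s running-mean `smoothed` track — the raw
magnitude ripples within each cardiac cycle because the band-passed
pulse is not narrowband — and the 60 s running-mean `baseline`.

## Detection

`process_recording()` chains the steps: demean, filter, detect beats
(`detect_beats()`, autocorrelation-guided peak picking with a prominence
gate), score 10 s half-overlapping windows and reject beats in windows
with periodicity below 0.5 (`reject_noisy_beats()`), then compute the
envelope. Samples in rejected windows are also **excluded from the
baseline mean**: a motion burst would otherwise inflate the baseline and
manufacture false "constriction" dips on either side of the burst.

`detect_events()` segments spans where
`100 * (1 - smoothed/baseline)` exceeds `min_depth_pct = 5`, requiring
each contiguous span to last `min_duration_s = 3` *before* merging gaps
shorter than 2 s (merging first lets sub-second ripple dips chain into
phantom events), at least one accepted beat inside the span, and no
overlap with a 6 s edge-exclusion margin (the FIR transient is 250
samples; the envelope needs a settled baseline). Each event reports
onset, nadir time, percent depth at nadir, and a size bin: `[0, 15)`
small, `[15, 30)` medium, `[30, 50]` large, with an `out_of_range` flag
above 50.

```{r detect}
an <- process_recording(sim$recording)
an$events
```

## Agreement statistics

For method comparison, `pair_events_by_time()` greedily matches events
from two sources within a 60 s window, then `agreement_report()`
combines: `confusion_agreement()` (percent of pairs placed in the same
size bin), `bland_altman()` (bias and $\pm 1.96\,\mathrm{SD}$ limits of
agreement, $n-1$ denominator), and `correlation_r2()` (squared Pearson
correlation). `two_sample_z()` is an unpaired, unequal-variance Z-test
on summary statistics for comparing event-depth populations; it reports
the standard two-tailed normal p-value.

## Validated behaviour and limits

The test suite and `scripts/acceptance.R` verify, among other things:
depth recovery within 3 percentage points (MAE ≈ 1.4) over 20 seeded
simulations at 10–40 % depth with correct bins away from boundaries;
zero false events over 20 default-noise null recordings; detection of
every programmed event in a 45-trial campaign; and closed-form checks
of every numeric primitive against independent oracles.

Known limits: events much longer than the defaults bias the unmasked
baseline upward (recovered depth $\approx d(1-u)/(1-du)$ where $u$ is
the fractional amplitude-seconds removed from the 60 s window); depths
at a bin boundary can land on either side; and the simulator's additive
Gaussian noise is a simplification of real motion and perfusion
variability.
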