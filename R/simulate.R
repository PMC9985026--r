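#' Pulse-shape parameters for the synthetic PPG template
#'
#' A single-beat PPG template built from two wrapped Gaussian lobes: a
#' dominant systolic lobe and a smaller, delayed diastolic lobe. All widths,
#' centers and delays are fractions of the beat period, so the template is a
#' function of beat phase in `[0, 1)` with continuous periodic continuation.
#' The template is normalised so its maximum equals `sys_amp`.
#'
#' @param sys_amp Systolic peak amplitude (arbitrary signal units).
#' @param sys_width Systolic lobe Gaussian SD, fraction of the period.
#' @param sys_center Systolic lobe center phase.
#' @param dia_amp Diastolic lobe amplitude, same units as `sys_amp` (0 gives
#'   a single-lobe wave).
#' @param dia_width Diastolic lobe Gaussian SD, fraction of the period.
#' @param dia_delay Diastolic lobe delay after the systolic center,
#'   fraction of the period.
#' @return A list of class `pulse_shape`.
#' @export
pulse_shape <- function(sys_amp = 1, sys_width = 0.08, sys_center = 0.2,
                        dia_amp = 0.35, dia_width = 0.12, dia_delay = 0.35) {
  if (sys_amp <= 0) stop_arg("sys_amp must be positive")
  if (sys_width <= 0 || dia_width <= 0) {
    stop_arg("pulse lobe widths must be positive")
  }
  if (dia_amp < 0) stop_arg("dia_amp must be non-negative")
  if (dia_delay < 0 || dia_delay >= 1) stop_arg("dia_delay must be in [0, 1)")
  structure(list(sys_amp = sys_amp, sys_width = sys_width,
                 sys_center = sys_center, dia_amp = dia_amp,
                 dia_width = dia_width, dia_delay = dia_delay),
            class = "pulse_shape")
}

# Raw (unnormalised) two-lobe template: sum of Gaussians wrapped over
# adjacent periods so the periodic continuation is smooth.
pulse_template_raw <- function(phase, shape) {
  g <- function(center, width, amp) {
    v <- 0
    for (wrap in -1:1) {
      v <- v + amp * exp(-0.5 * ((phase - center - wrap) / width)^2)
    }
    v
  }
  g(shape$sys_center, shape$sys_width, shape$sys_amp) +
    g(shape$sys_center + shape$dia_delay, shape$dia_width, shape$dia_amp)
}

#' Evaluate the single-beat pulse template
#'
#' @param phase Beat phase, values in `[0, 1)` (fraction of the cardiac
#'   cycle). Vectorised.
#' @param shape A [pulse_shape].
#' @return Amplitudes, same length as `phase`; the maximum over one period
#'   equals `shape$sys_amp`.
#' @examples
#' ph <- seq(0, 1, length.out = 200)
#' amp <- pulse_template(ph[-200], pulse_shape())
#' @export
pulse_template <- function(phase, shape = pulse_shape()) {
  if (!inherits(shape, "pulse_shape")) shape <- do.call(pulse_shape, shape)
  if (any(phase < 0 | phase >= 1)) stop_arg("phase must lie in [0, 1)")
  # normalise on a fixed dense grid so the systolic peak equals sys_amp
  grid <- seq(0, 1, length.out = 4096L + 1L)[-(4096L + 1L)]
  peak <- max(pulse_template_raw(grid, shape))
  pulse_template_raw(phase, shape) * (shape$sys_amp / peak)
}

#' Specify one programmed vasoconstriction event
#'
#' Event kinetics are piecewise: an exponential amplitude fall with time
#' constant `onset_tau_s`, a plateau of duration `plateau_s` at the maximal
#' constriction depth, then an exponential recovery with `recovery_tau_s`.
#' A small `recovery_tau_s` gives a rapid-onset/rapid-termination morphology;
#' a large one gives the rapid-onset/elongated-recovery morphology.
#'
#' @param onset_s Event start time in seconds.
#' @param depth_pct Programmed constriction depth in percent, `[0, 100]`:
#'   the pulsatile amplitude at the nadir is `1 - depth_pct/100` of baseline.
#' @param onset_tau_s Time constant of the amplitude fall, seconds.
#' @param recovery_tau_s Time constant of the amplitude recovery, seconds.
#' @param plateau_s Duration held at maximal constriction, seconds.
#'
#' @details Defaults give a compact episode (about 13 s from onset to full
#' recovery), short against the 60 s running-average baseline, so the
#' programmed depth is recoverable from the envelope without baseline
#' masking. Longer events sag the literal running-average baseline and are
#' systematically under-estimated; see the methods vignette.
#' @return A list of class `vaso_event_spec`.
#' @export
vaso_event_spec <- function(onset_s, depth_pct, onset_tau_s = 0.5,
                            recovery_tau_s = 1, plateau_s = 3) {
  assert_scalar_num(onset_s, "onset_s", lo = 0)
  assert_scalar_num(depth_pct, "depth_pct", lo = 0, hi = 100)
  if (onset_tau_s <= 0 || recovery_tau_s <= 0) {
    stop_arg("event time constants must be positive")
  }
  assert_scalar_num(plateau_s, "plateau_s", lo = 0)
  structure(list(onset_s = onset_s, depth_pct = depth_pct,
                 onset_tau_s = onset_tau_s, recovery_tau_s = recovery_tau_s,
                 plateau_s = plateau_s),
            class = "vaso_event_spec")
}

# Fall phase is truncated at FALL_TAUS time constants, where the envelope is
# within exp(-FALL_TAUS) ~ 9e-4 of the plateau value; the plateau then sits
# exactly at 1 - depth so the programmed depth is recoverable exactly.
FALL_TAUS <- 7
RECOVERY_TAUS <- 7

event_extent_s <- function(ev) {
  c(ev$onset_s,
    ev$onset_s + FALL_TAUS * ev$onset_tau_s + ev$plateau_s +
      RECOVERY_TAUS * ev$recovery_tau_s)
}

# Multiplicative amplitude modulation in (0, 1] for one event, evaluated at
# times t (seconds).
event_modulation <- function(t, ev) {
  d <- ev$depth_pct / 100
  t_fall_end <- ev$onset_s + FALL_TAUS * ev$onset_tau_s
  t_plateau_end <- t_fall_end + ev$plateau_s
  a <- rep(1, length(t))
  fall <- t >= ev$onset_s & t < t_fall_end
  a[fall] <- 1 - d * (1 - exp(-(t[fall] - ev$onset_s) / ev$onset_tau_s))
  plat <- t >= t_fall_end & t < t_plateau_end
  a[plat] <- 1 - d
  rec <- t >= t_plateau_end
  a[rec] <- 1 - d * exp(-(t[rec] - t_plateau_end) / ev$recovery_tau_s)
  a
}

#' Configure a synthetic dual-channel PPG simulation
#'
#' The generator emulates the chest-worn device's recordings: quasi-periodic
#' pulse waves at a physiological heart rate with cycle-to-cycle jitter,
#' respiration baseline wander, programmable vasoconstriction episodes as
#' multiplicative amplitude attenuation, additive motion-artifact transients,
#' additive white noise, an IR channel with larger pulsatile amplitude than
#' red, a large positive DC offset, and quantisation to unsigned ADC counts
#' at a nominal 50 Hz.
#'
#' @param duration_s Recording length, seconds.
#' @param rate_hz Sampling rate, samples/s (device nominal 50).
#' @param hr_bpm Mean heart rate, beats per minute, in `[30, 220]`.
#' @param hr_jitter_pct Cycle-to-cycle beat-period jitter SD, percent of the
#'   mean period.
#' @param shape A [pulse_shape] (or list of its arguments).
#' @param ir_red_ratio IR:red pulsatile amplitude ratio, must be `>= 1`.
#' @param resp_rate_bpm,resp_amp_frac Respiration baseline-wander sinusoid:
#'   rate in breaths/min and amplitude as a fraction of the systolic pulse
#'   amplitude.
#' @param noise_sd_frac Additive white-noise SD as a fraction of the
#'   systolic pulse amplitude.
#' @param artifact_schedule List of `c(time_s, duration_s, magnitude)`
#'   triplets; each adds a half-sine transient of the given duration whose
#'   peak is `magnitude` times the systolic pulse amplitude.
#' @param event_schedule List of [vaso_event_spec] objects; must be
#'   non-overlapping and lie within the recording.
#' @param pulse_amp_counts Systolic pulse amplitude in ADC counts.
#' @param dc_offset_counts DC offset in ADC counts added before quantisation
#'   so counts are unsigned, as an ADC produces.
#' @param adc_bits Quantisation depth (default 18).
#' @param seed RNG seed; one RNG stream per recording, drawn in a fixed
#'   documented order (beat jitter first, then red noise, then IR noise).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 300, rate_hz = 50, hr_bpm = 60,
                       hr_jitter_pct = 3, shape = pulse_shape(),
                       ir_red_ratio = 1.8, resp_rate_bpm = 15,
                       resp_amp_frac = 0.1, noise_sd_frac = 0.05,
                       artifact_schedule = list(), event_schedule = list(),
                       pulse_amp_counts = 4000, dc_offset_counts = 2^17,
                       adc_bits = 18, seed = 1L) {
  assert_scalar_num(duration_s, "duration_s", lo = 1e-9)
  assert_scalar_num(rate_hz, "rate_hz", lo = 1e-9)
  assert_scalar_num(hr_bpm, "hr_bpm", lo = 30, hi = 220)
  assert_scalar_num(hr_jitter_pct, "hr_jitter_pct", lo = 0, hi = 50)
  if (ir_red_ratio < 1) stop_arg("ir_red_ratio must be >= 1")
  assert_scalar_num(resp_rate_bpm, "resp_rate_bpm", lo = 0)
  assert_scalar_num(resp_amp_frac, "resp_amp_frac", lo = 0)
  assert_scalar_num(noise_sd_frac, "noise_sd_frac", lo = 0)
  if (!inherits(shape, "pulse_shape")) shape <- do.call(pulse_shape, shape)
  events <- lapply(event_schedule, function(e) {
    if (!inherits(e, "vaso_event_spec")) e <- do.call(vaso_event_spec, e)
    e
  })
  if (length(events)) {
    ext <- t(vapply(events, event_extent_s, numeric(2)))
    ord <- order(ext[, 1])
    ext <- ext[ord, , drop = FALSE]
    events <- events[ord]
    if (any(ext[, 1] < 0) ||
        any(vapply(events, function(e) e$onset_s, 0) > duration_s)) {
      stop_arg("event_schedule entries must lie within [0, duration_s]")
    }
    if (nrow(ext) > 1L && any(ext[-nrow(ext), 2] > ext[-1, 1])) {
      stop_arg("event_schedule entries overlap in time")
    }
  }
  structure(
    list(duration_s = duration_s, rate_hz = rate_hz, hr_bpm = hr_bpm,
         hr_jitter_pct = hr_jitter_pct, shape = shape,
         ir_red_ratio = ir_red_ratio, resp_rate_bpm = resp_rate_bpm,
         resp_amp_frac = resp_amp_frac, noise_sd_frac = noise_sd_frac,
         artifact_schedule = artifact_schedule, event_schedule = events,
         pulse_amp_counts = pulse_amp_counts,
         dc_offset_counts = dc_offset_counts, adc_bits = adc_bits,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a dual-channel PPG recording with known ground truth
#'
#' Runs the generator described in [sim_config()]. The pulsatile waveform is
#' multiplied by the per-sample event amplitude envelope; the IR channel's
#' AC component is the red AC component scaled by `ir_red_ratio` (with an
#' independent noise draw); both channels share the DC offset and are
#' quantised to `adc_bits` unsigned counts. Identical seeds give identical
#' output.
#'
#' @param config A [sim_config].
#' @param quantize If `FALSE`, return ideal (unquantised, unclipped) sample
#'   values instead of ADC counts; useful for numerical validation.
#' @return A list with elements `recording` (a [ppg_recording]) and `truth`
#'   (ground truth: `events`, a data frame with `onset_s`, `nadir_s`,
#'   `depth_pct`, `bin`; `amplitude_envelope`, the per-sample multiplicative
#'   modulation in `(0, 1]`; and `beat_times_s`).
#' @examples
#' sim <- simulate_recording(sim_config(duration_s = 30, seed = 7))
#' sim$recording
#' @export
simulate_recording <- function(config, quantize = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  # Gaussian systolic lobe of SD sys_width*period has ~all energy below
  # 3/(2*pi*sigma) Hz; warn when the sample rate dips under twice that
  sigma_s <- config$shape$sys_width * 60 / config$hr_bpm
  bw_hz <- 3 / (2 * pi * sigma_s)
  if (config$rate_hz <= 2 * bw_hz) {
    warning(sprintf("rate_hz %g is at or below twice the pulse bandwidth (%.1f Hz); waveform will be undersampled",
                    config$rate_hz, bw_hz), call. = FALSE)
  }
  n <- round(config$duration_s * config$rate_hz)
  t <- (seq_len(n) - 1L) / config$rate_hz
  amp <- config$pulse_amp_counts

  with_seed(config$seed, {
    # 1) beat-period jitter
    mean_period <- 60 / config$hr_bpm
    n_beats <- ceiling(config$duration_s / mean_period) + 2L
    periods <- mean_period *
      (1 + stats::rnorm(n_beats, 0, config$hr_jitter_pct / 100))
    periods <- pmax(periods, 0.2 * mean_period)
    beat_starts <- c(0, cumsum(periods))
    while (beat_starts[length(beat_starts)] < config$duration_s) {
      p <- mean_period *
        (1 + stats::rnorm(1, 0, config$hr_jitter_pct / 100))
      beat_starts <- c(beat_starts,
                       beat_starts[length(beat_starts)] + max(p, 0.2 * mean_period))
    }
    idx <- findInterval(t, beat_starts)
    phase <- (t - beat_starts[idx]) / (beat_starts[idx + 1L] - beat_starts[idx])
    phase <- pmin(pmax(phase, 0), 1 - 1e-12)

    shape_counts <- config$shape
    shape_counts$sys_amp <- amp * config$shape$sys_amp
    shape_counts$dia_amp <- amp * config$shape$dia_amp
    pulse <- pulse_template(phase, shape_counts)

    env_mod <- rep(1, n)
    for (ev in config$event_schedule) {
      env_mod <- env_mod * event_modulation(t, ev)
    }

    resp <- config$resp_amp_frac * amp *
      sin(2 * pi * config$resp_rate_bpm / 60 * t)

    artifact <- numeric(n)
    for (a in config$artifact_schedule) {
      in_a <- t >= a[1] & t < a[1] + a[2]
      artifact[in_a] <- artifact[in_a] +
        a[3] * amp * sin(pi * (t[in_a] - a[1]) / a[2])
    }

    ac <- pulse * env_mod + resp + artifact
    # 2) red channel noise, 3) IR channel noise
    noise_red <- stats::rnorm(n, 0, config$noise_sd_frac * amp)
    noise_ir <- stats::rnorm(n, 0, config$noise_sd_frac * amp)
    red <- config$dc_offset_counts + ac + noise_red
    ir <- config$dc_offset_counts + config$ir_red_ratio * ac + noise_ir

    if (quantize) {
      cmax <- 2^config$adc_bits - 1
      red <- pmin(pmax(round(red), 0), cmax)
      ir <- pmin(pmax(round(ir), 0), cmax)
    }

    events <- if (length(config$event_schedule)) {
      do.call(rbind, lapply(config$event_schedule, function(ev) {
        nadir <- ev$onset_s + FALL_TAUS * ev$onset_tau_s + ev$plateau_s / 2
        data.frame(onset_s = ev$onset_s, nadir_s = nadir,
                   depth_pct = ev$depth_pct,
                   bin = as.character(classify_event(ev$depth_pct)),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(onset_s = numeric(0), nadir_s = numeric(0),
                 depth_pct = numeric(0), bin = character(0),
                 stringsAsFactors = FALSE)
    }

    rec <- if (quantize) {
      ppg_recording(t, red, ir, rate_hz = config$rate_hz,
                    adc_bits = config$adc_bits,
                    meta = list(source = "simulated", seed = config$seed))
    } else {
      structure(list(timestamp_s = t, red = red, ir = ir,
                     rate_hz = config$rate_hz, adc_bits = config$adc_bits,
                     meta = list(source = "simulated-ideal",
                                 seed = config$seed)),
                class = "ppg_recording")
    }
    list(recording = rec,
         truth = list(events = events, amplitude_envelope = env_mod,
                      beat_times_s = beat_starts[beat_starts <= config$duration_s]))
  })
}
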