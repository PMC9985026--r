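#' Detection configuration
#'
#' Thresholds governing beat acceptance and event segmentation. None of
#' these are dictated by the sensor; they separate genuine constriction
#' episodes from beat-scale envelope ripple and are all overridable.
#'
#' @param periodicity_threshold Minimum window periodicity score for beats
#'   in that window to be accepted (default 0.5).
#' @param min_depth_pct Minimum percent constriction for a span to count as
#'   an event (default 5).
#' @param min_duration_s Minimum time the envelope/baseline ratio must stay
#'   below threshold (default 3 s).
#' @param merge_gap_s Events separated by less than this are merged
#'   (default 2 s).
#' @param channel Channel analysed by the pipeline, `"ir"` (default; the IR
#'   signal has the larger pulsatile amplitude and higher repeatability) or
#'   `"red"`.
#' @param window_s,window_overlap Periodicity assessment window length in
#'   seconds and fractional overlap (defaults 10 s, 0.5).
#' @param edge_exclude_s Margin at each end of the recording excluded from
#'   event segmentation (default 6 s), covering the FIR edge transient and
#'   envelope settling.
#' @param hr_range_bpm Heart-rate search range, beats/min.
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(periodicity_threshold = 0.5, min_depth_pct = 5,
                          min_duration_s = 3, merge_gap_s = 2,
                          channel = c("ir", "red"), window_s = 10,
                          window_overlap = 0.5, edge_exclude_s = 6,
                          hr_range_bpm = c(40, 180)) {
  channel <- match.arg(channel)
  assert_scalar_num(periodicity_threshold, "periodicity_threshold",
                    lo = 0, hi = 1)
  assert_scalar_num(min_depth_pct, "min_depth_pct", lo = 0, hi = 100)
  assert_scalar_num(min_duration_s, "min_duration_s", lo = 0)
  assert_scalar_num(merge_gap_s, "merge_gap_s", lo = 0)
  assert_scalar_num(window_s, "window_s", lo = 1)
  assert_scalar_num(window_overlap, "window_overlap", lo = 0, hi = 0.95)
  assert_scalar_num(edge_exclude_s, "edge_exclude_s", lo = 0)
  structure(list(periodicity_threshold = periodicity_threshold,
                 min_depth_pct = min_depth_pct,
                 min_duration_s = min_duration_s, merge_gap_s = merge_gap_s,
                 channel = channel, window_s = window_s,
                 window_overlap = window_overlap,
                 edge_exclude_s = edge_exclude_s,
                 hr_range_bpm = hr_range_bpm),
            class = "detect_config")
}

#' Detect systolic beat peaks
#'
#' Local maxima of the band-passed signal with a minimum separation of
#' `60 * rate_hz / max(hr_range_bpm)` samples (closely spaced candidates
#' resolved in favour of the higher peak) and a prominence gate: a peak
#' must rise above `prominence_frac` times the local running envelope, so
#' isolated baseline excursions do not create beats.
#'
#' @param filtered_signal Band-passed PPG samples.
#' @param rate_hz Sampling rate, Hz.
#' @param hr_range_bpm Heart-rate range, beats/min.
#' @param prominence_frac Fraction of the 10 s running envelope a peak must
#'   exceed (default 0.4).
#' @return An object of class `beat_series`: list with `peak_indices`
#'   (strictly increasing sample indices), `accepted` (logical mask, all
#'   `TRUE` until [reject_noisy_beats()] runs) and `window_scores` (`NULL`
#'   here). Empty, with a warning, when no beats are found.
#' @export
detect_beats <- function(filtered_signal, rate_hz,
                         hr_range_bpm = c(40, 180), prominence_frac = 0.4) {
  x <- as.numeric(filtered_signal)
  min_sep <- floor(60 * rate_hz / max(hr_range_bpm))
  cand <- local_maxima(x)
  empty <- structure(list(peak_indices = integer(0), accepted = logical(0),
                          window_scores = NULL, rate_hz = rate_hz),
                     class = "beat_series")
  if (!length(cand)) {
    warning("no beats found", call. = FALSE)
    return(empty)
  }
  env <- analytic_envelope(x)
  base <- running_mean(env, 10, rate_hz)
  cand <- cand[x[cand] > prominence_frac * base[cand]]
  if (!length(cand)) {
    warning("no beats found", call. = FALSE)
    return(empty)
  }
  # enforce minimum separation, keeping the taller of conflicting peaks
  ord <- cand[order(-x[cand])]
  keep <- logical(length(x))
  blocked <- logical(length(x))
  for (i in ord) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      lo <- max(1L, i - min_sep)
      hi <- min(length(x), i + min_sep)
      blocked[lo:hi] <- TRUE
    }
  }
  peaks <- which(keep)
  structure(list(peak_indices = peaks,
                 accepted = rep(TRUE, length(peaks)),
                 window_scores = NULL, rate_hz = rate_hz),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %d accepted\n",
              length(x$peak_indices), sum(x$accepted)))
  invisible(x)
}

#' Reject noisy beats by windowed periodicity
#'
#' Splits the signal into sliding windows (10 s, 50% overlap by default),
#' scores each with [periodicity_score()], and marks every beat contained in
#' a window scoring below `config$periodicity_threshold` as rejected. A
#' window where no beat period can be estimated (pure noise) also rejects
#' its beats. Peak indices are unchanged; only the acceptance mask is
#' updated.
#'
#' @param signal The band-passed signal the beats were detected on.
#' @param beats A `beat_series` from [detect_beats()].
#' @param config A [detect_config()].
#' @return The `beat_series` with `accepted` updated and `window_scores`
#'   set to a data frame (`start_s`, `end_s`, `score`).
#' @export
reject_noisy_beats <- function(signal, beats, config = detect_config()) {
  stopifnot(inherits(beats, "beat_series"))
  rate <- beats$rate_hz
  n <- length(signal)
  wlen <- round(config$window_s * rate)
  step <- max(1L, round(wlen * (1 - config$window_overlap)))
  starts <- seq(1L, max(1L, n - wlen + 1L), by = step)
  scores <- numeric(length(starts))
  accepted <- rep(TRUE, length(beats$peak_indices))
  for (j in seq_along(starts)) {
    idx <- starts[j]:min(n, starts[j] + wlen - 1L)
    sc <- tryCatch(
      periodicity_score(signal[idx], rate,
                        hr_range_bpm = config$hr_range_bpm)$score,
      error = function(e) 0)
    scores[j] <- sc
    if (sc < config$periodicity_threshold) {
      inside <- beats$peak_indices >= idx[1L] &
        beats$peak_indices <= idx[length(idx)]
      accepted[inside] <- FALSE
    }
  }
  beats$accepted <- accepted
  beats$window_scores <- data.frame(
    start_s = (starts - 1L) / rate,
    end_s = (pmin(n, starts + wlen - 1L) - 1L) / rate,
    score = scores)
  if (length(accepted) && !any(accepted)) {
    warning("all beats rejected by the periodicity gate", call. = FALSE)
  }
  beats
}

#' Percent vasoconstriction at envelope minima
#'
#' The constriction statistic: each local envelope minimum is referenced to
#' the 60 s running-average baseline, and the percent constriction is the
#' complementary ratio
#' `100 * (1 - envelope[i] / baseline[i])`, clipped to `[0, 100]`. The raw
#' ratio (near 1 at rest, smaller during constriction) is retained for
#' transparency.
#'
#' @param envelope An [envelope_series()].
#' @param minima_indices Sample indices of the envelope local minima to
#'   evaluate.
#' @param on Which envelope track the minima are read from: `"smoothed"`
#'   (default; per-beat perfusion amplitude, free of within-cycle ripple)
#'   or `"values"` (raw analytic magnitude).
#' @return Data frame with `index`, `time_s`, `ratio`, `percent`.
#' @export
percent_vasoconstriction <- function(envelope, minima_indices,
                                     on = c("smoothed", "values")) {
  stopifnot(inherits(envelope, "envelope_series"))
  on <- match.arg(on)
  env <- envelope[[on]]
  i <- as.integer(minima_indices)
  if (any(i < 1L | i > length(env))) {
    stop_arg("minima indices out of range")
  }
  base <- envelope$baseline[i]
  if (any(base <= 0)) {
    stop_arg("undefined ratio: baseline is zero at minimum index %d",
             i[which(base <= 0)[1L]])
  }
  ratio <- env[i] / base
  percent <- pmin(pmax(100 * (1 - ratio), 0), 100)
  data.frame(index = i, time_s = (i - 1L) / envelope$rate_hz,
             ratio = ratio, percent = percent)
}

#' Bin a percent constriction as small, medium or large
#'
#' Half-open bins: `[0, 15)` small, `[15, 30)` medium, `[30, 50]` large.
#' Values above 50 are still labelled large but flagged out of range in the
#' `"out_of_range"` attribute.
#'
#' @param percent_constriction Percent values in `[0, 100]` (vectorised).
#' @return Factor with levels `small`, `medium`, `large` and logical
#'   attribute `out_of_range`.
#' @examples
#' classify_event(c(10, 20, 40))
#' @export
classify_event <- function(percent_constriction) {
  p <- percent_constriction
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_arg("percent_constriction must be non-negative and finite")
  }
  bin <- ifelse(p < 15, "small", ifelse(p < 30, "medium", "large"))
  out <- factor(bin, levels = c("small", "medium", "large"))
  attr(out, "out_of_range") <- p > 50
  out
}

#' Segment vasoconstriction events from the envelope
#'
#' Contiguous spans where the beat-scale smoothed envelope over the 60 s
#' baseline, `smoothed/baseline`, stays below `1 - min_depth_pct/100` for at
#' least `min_duration_s`, containing at least one accepted beat, become
#' events; spans separated by less than `merge_gap_s` are merged first. The
#' nadir is the span's envelope/baseline minimum; the percent constriction
#' there comes from [percent_vasoconstriction()] and the size bin from
#' [classify_event()]. Spans overlapping the `edge_exclude_s` margin at
#' either end of the recording are discarded (filter edge transients).
#'
#' @param envelope An [envelope_series()].
#' @param beats A `beat_series` (after [reject_noisy_beats()] if noise
#'   gating is wanted).
#' @param config A [detect_config()].
#' @return Data frame of events: `onset_s`, `nadir_s`, `end_s`,
#'   `percent`, `bin`, `channel` (zero rows when none qualify).
#' @export
detect_events <- function(envelope, beats, config = detect_config()) {
  stopifnot(inherits(envelope, "envelope_series"))
  rate <- envelope$rate_hz
  n <- length(envelope$values)
  ratio <- envelope$smoothed / ifelse(envelope$baseline > 0,
                                      envelope$baseline, NA_real_)
  below <- !is.na(ratio) & ratio < 1 - config$min_depth_pct / 100
  edge <- round(config$edge_exclude_s * rate)
  if (edge > 0) {
    below[seq_len(min(edge, n))] <- FALSE
    below[seq.int(max(1L, n - edge + 1L), n)] <- FALSE
  }
  no_events <- data.frame(onset_s = numeric(0), nadir_s = numeric(0),
                          end_s = numeric(0), percent = numeric(0),
                          bin = character(0), channel = character(0),
                          stringsAsFactors = FALSE)
  if (!any(below)) return(no_events)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- cbind(starts[r$values], ends[r$values])
  # duration gate first: each contiguous below-threshold span must last
  # min_duration_s on its own, so sub-second ripple dips cannot chain into
  # a qualifying event via merging
  min_len <- config$min_duration_s * rate
  spans <- spans[spans[, 2L] - spans[, 1L] + 1L >= min_len, , drop = FALSE]
  if (!nrow(spans)) return(no_events)
  # then merge qualifying spans separated by < merge_gap_s
  gap <- round(config$merge_gap_s * rate)
  if (nrow(spans) > 1L) {
    merged <- spans[1L, , drop = FALSE]
    for (k in 2:nrow(spans)) {
      if (spans[k, 1L] - merged[nrow(merged), 2L] < gap) {
        merged[nrow(merged), 2L] <- spans[k, 2L]
      } else {
        merged <- rbind(merged, spans[k, ])
      }
    }
    spans <- merged
  }
  rows <- list()
  accepted_peaks <- beats$peak_indices[beats$accepted]
  for (k in seq_len(nrow(spans))) {
    a <- spans[k, 1L]; b <- spans[k, 2L]
    if (!any(accepted_peaks >= a & accepted_peaks <= b)) next
    nadir <- a - 1L + which.min(ratio[a:b])
    pv <- percent_vasoconstriction(envelope, nadir, on = "smoothed")
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = (a - 1L) / rate, nadir_s = (nadir - 1L) / rate,
      end_s = (b - 1L) / rate, percent = pv$percent,
      bin = as.character(classify_event(pv$percent)),
      channel = config$channel, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(no_events)
  do.call(rbind, rows)
}

#' Run the full detection chain on one recording
#'
#' Band-pass filter, analytic envelope with 60 s baseline, beat detection,
#' periodicity-based noise rejection, and event segmentation, on the
#' configured channel.
#'
#' @param recording A [ppg_recording].
#' @param fspec A [filter_spec()]; its `rate_hz` is overridden by the
#'   recording's rate.
#' @param config A [detect_config()].
#' @return A list of class `ppg_analysis`: `filtered`, `envelope`
#'   (an `envelope_series`), `beats` (a `beat_series`), `events` (data
#'   frame), `channel`, `rate_hz`.
#' @examples
#' sim <- simulate_recording(sim_config(
#'   duration_s = 180, seed = 3,
#'   event_schedule = list(vaso_event_spec(onset_s = 90, depth_pct = 30))))
#' an <- process_recording(sim$recording)
#' an$events
#' @export
process_recording <- function(recording, fspec = filter_spec(),
                              config = detect_config()) {
  stopifnot(inherits(recording, "ppg_recording"))
  fspec$rate_hz <- recording$rate_hz
  x <- recording[[config$channel]]
  h <- design_fir(fspec)
  # demean first: the band-pass kills DC in steady state, but a raw ADC
  # offset (~2^17 counts) would drive an enormous step response at the edges
  filt <- filter_signal(x - mean(x), h)
  beats <- detect_beats(as.numeric(filt), recording$rate_hz,
                        hr_range_bpm = config$hr_range_bpm)
  noisy <- NULL
  if (length(beats$peak_indices)) {
    beats <- reject_noisy_beats(as.numeric(filt), beats, config)
    # low-periodicity windows are excluded from the perfusion baseline:
    # a motion transient must not inflate the 60 s average around itself
    ws <- beats$window_scores
    bad <- ws[ws$score < config$periodicity_threshold, , drop = FALSE]
    if (nrow(bad)) {
      noisy <- logical(length(filt))
      for (k in seq_len(nrow(bad))) {
        lo <- round(bad$start_s[k] * recording$rate_hz) + 1L
        hi <- min(length(filt), round(bad$end_s[k] * recording$rate_hz) + 1L)
        noisy[lo:hi] <- TRUE
      }
    }
  }
  env <- envelope_series(as.numeric(filt), recording$rate_hz,
                         exclude = noisy)
  events <- detect_events(env, beats, config)
  structure(list(filtered = as.numeric(filt), envelope = env, beats = beats,
                 events = events, channel = config$channel,
                 rate_hz = recording$rate_hz),
            class = "ppg_analysis")
}

#' @export
print.ppg_analysis <- function(x, ...) {
  cat(sprintf("<ppg_analysis> channel %s, %d beats (%d accepted), %d event(s)\n",
              x$channel, length(x$beats$peak_indices), sum(x$beats$accepted),
              nrow(x$events)))
  invisible(x)
}

#' Summarise detection over repeated trials
#'
#' Tallies how many trials produced at least one detected event and reports
#' the detection rate as an integer percent (e.g. 41 detected of 45 trials
#' gives 91).
#'
#' @param events_per_trial Integer vector: number of detected events in each
#'   trial.
#' @return List with `detected`, `total`, `percent` (integer-rounded).
#' @export
trial_detection_summary <- function(events_per_trial) {
  if (!length(events_per_trial)) stop_arg("no trials supplied")
  detected <- as.integer(sum(events_per_trial > 0))
  total <- length(events_per_trial)
  list(detected = detected, total = total,
       percent = as.integer(round(100 * detected / total)))
}
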