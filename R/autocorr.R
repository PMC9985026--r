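#' Biased sample autocorrelation
#'
#' Computes the biased autocovariance
#' \deqn{c_k = \frac{1}{T} \sum_{t=1}^{T-k} (g(t) - \bar g)(g(t+k) - \bar g)}
#' and the autocorrelation \eqn{r(k) = c_k / c_0}, where \eqn{c_0} is the
#' sample variance (1/T denominator at every lag, so \eqn{|r(k)| \le 1} and
#' \eqn{r(0) = 1} exactly). This is the repeatability primitive behind the
#' periodicity score.
#'
#' @param signal Numeric vector, length at least `max_lag + 2`, with nonzero
#'   variance.
#' @param max_lag Largest lag (samples) to compute.
#' @return An object of class `autocorr_series`: list with `lags`
#'   (`0:max_lag`), `values` (`r(k)`), and `sample_count` (`T`).
#' @examples
#' r <- biased_autocorrelation(sin(2 * pi * (1:500) / 50), max_lag = 100)
#' r$values[1]   # r(0) == 1
#' @export
biased_autocorrelation <- function(signal, max_lag) {
  T_ <- length(signal)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || T_ < max_lag + 2L) {
    stop_arg("signal length %d too short for max_lag %d", T_, max_lag)
  }
  y <- signal - mean(signal)
  c0 <- sum(y * y) / T_
  if (c0 == 0) {
    stop_arg("degenerate input: signal has zero variance")
  }
  ck <- vapply(0:max_lag, function(k) {
    sum(y[seq_len(T_ - k)] * y[seq.int(k + 1L, T_)]) / T_
  }, numeric(1))
  structure(list(lags = 0:max_lag, values = ck / c0, sample_count = T_),
            class = "autocorr_series")
}

#' @export
print.autocorr_series <- function(x, ...) {
  cat(sprintf("<autocorr_series> lags 0..%d over %d samples\n",
              max(x$lags), x$sample_count))
  invisible(x)
}

#' Estimate the beat period from the autocorrelation
#'
#' Finds the lag of the maximal autocorrelation peak inside the
#' physiological lag window implied by the heart-rate range
#' (`[60*rate/hr_max, 60*rate/hr_min]` samples).
#'
#' @param signal Band-passed PPG samples.
#' @param rate_hz Sampling rate, Hz.
#' @param hr_range_bpm Two-element heart-rate search range in beats/min.
#' @param min_peak Minimum autocorrelation value for a lag to count as a
#'   beat peak; below this the signal is declared aperiodic.
#' @return Beat period in samples (integer).
#' @export
estimate_beat_period <- function(signal, rate_hz, hr_range_bpm = c(40, 180),
                                 min_peak = 0.15) {
  stopifnot(length(hr_range_bpm) == 2L, hr_range_bpm[1] < hr_range_bpm[2])
  lag_min <- max(2L, floor(60 * rate_hz / hr_range_bpm[2]))
  lag_max <- ceiling(60 * rate_hz / hr_range_bpm[1])
  ac <- biased_autocorrelation(signal, max_lag = min(lag_max + 1L,
                                                     length(signal) - 2L))
  r <- ac$values
  win <- seq.int(lag_min, min(lag_max, length(r) - 2L)) + 1L  # 1-based index
  if (!length(win)) stop_arg("signal too short for the heart-rate window")
  best <- win[which.max(r[win])]
  # must be a genuine positive peak, not noise
  if (r[best] < min_peak) {
    stop_arg("no beat found: no autocorrelation peak above %.2f in the %g-%g bpm window",
             min_peak, hr_range_bpm[1], hr_range_bpm[2])
  }
  as.integer(best - 1L)
}

#' Periodicity (repeatability) score of a quasi-periodic signal
#'
#' The signal-quality surrogate used to gate beats: the mean of the
#' autocorrelation local maxima found near integer multiples (1..`n_beat_lags`)
#' of the estimated beat period, divided by the zero-lag value (which is 1
#' for the biased estimator). A clean, repeatable pulse train scores near 1;
#' noise-dominated windows score near 0.
#'
#' @param signal Band-passed PPG samples, long enough to span
#'   `n_beat_lags` beat periods.
#' @param rate_hz Sampling rate, Hz.
#' @param n_beat_lags Number of beat-multiple lags averaged (default 3).
#' @param hr_range_bpm Heart-rate search range, beats/min.
#' @param peak_tol_frac Search half-width around each beat-lag multiple, as
#'   a fraction of the beat period (default 0.15, accommodating heart-rate
#'   variability).
#' @return An object of class `periodicity_score`: list with `score`
#'   (dimensionless, in `[-1, 1]`, practically `[0, 1]`),
#'   `beat_period_samples`, and `n_beat_lags`.
#' @examples
#' x <- sin(2 * pi * (1:2000) / 50)
#' periodicity_score(x, rate_hz = 50)$score
#' @export
periodicity_score <- function(signal, rate_hz, n_beat_lags = 3,
                              hr_range_bpm = c(40, 180),
                              peak_tol_frac = 0.15) {
  p <- estimate_beat_period(signal, rate_hz, hr_range_bpm)
  max_lag <- min(ceiling(n_beat_lags * p * (1 + peak_tol_frac)) + 1L,
                 length(signal) - 2L)
  if (max_lag < p) stop_arg("signal too short for %d beat lags", n_beat_lags)
  ac <- biased_autocorrelation(signal, max_lag = max_lag)
  r <- ac$values
  used <- 0L
  peaks <- numeric(0)
  for (m in seq_len(n_beat_lags)) {
    lo <- max(1L, floor(m * p * (1 - peak_tol_frac)))
    hi <- min(length(r) - 1L, ceiling(m * p * (1 + peak_tol_frac)))
    if (lo >= hi) break
    seg <- r[(lo:hi) + 1L]
    peaks <- c(peaks, max(seg))
    used <- used + 1L
  }
  if (!used) stop_arg("no beat-lag peaks available")
  structure(list(score = mean(peaks), beat_period_samples = p,
                 n_beat_lags = used),
            class = "periodicity_score")
}

#' @export
print.periodicity_score <- function(x, ...) {
  cat(sprintf("<periodicity_score> %.3f (beat period %d samples, %d lags)\n",
              x$score, x$beat_period_samples, x$n_beat_lags))
  invisible(x)
}
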