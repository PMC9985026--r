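# Independent oracles, deliberately implemented differently from the package.

# O(T*K) double-loop biased autocorrelation.
oracle_autocorr <- function(x, max_lag) {
  T_ <- length(x)
  xb <- mean(x)
  c0 <- 0
  for (t in 1:T_) c0 <- c0 + (x[t] - xb)^2
  c0 <- c0 / T_
  r <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    s <- 0
    if (k < T_) for (t in 1:(T_ - k)) s <- s + (x[t] - xb) * (x[t + k] - xb)
    r[k + 1] <- (s / T_) / c0
  }
  r
}

# Fixed 60-term power series for I0(z).
oracle_bessel_i0 <- function(z) {
  s <- 0
  for (m in 0:60) s <- s + (z / 2)^(2 * m) / factorial(m)^2
  s
}

# Direct DTFT magnitude of an FIR at frequency f (Hz).
oracle_dtft_gain <- function(h, f, rate_hz) {
  n <- seq_along(h) - 1
  Mod(sum(h * exp(-2i * pi * f * n / rate_hz)))
}

# Running mean via explicit per-index window averaging (no cumsum).
oracle_running_mean <- function(x, w) {
  n <- length(x)
  hl <- ceiling((w - 1) / 2)
  hr <- floor((w - 1) / 2)
  vapply(seq_len(n), function(i) {
    if (i - 1 >= hl && n - i >= hr) {
      mean(x[(i - hl):(i + hr)])
    } else {
      h <- min(i - 1, n - i)
      mean(x[(i - min(h, hl)):(i + min(h, hr))])
    }
  }, numeric(1))
}

# Peak finding by thresholded runs: each maximal run of samples above the
# given quantile contributes its argmax. Independent of detect_beats.
oracle_find_peaks <- function(x, q = 0.75) {
  thr <- stats::quantile(x, q)
  above <- x > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer(0)
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    out <- c(out, seg[which.max(x[seg])])
  }
  out
}

# Standard normal CDF through an erf Taylor series (converges fast for
# moderate |z|), independent of pnorm.
oracle_norm_cdf <- function(z) {
  x <- z / sqrt(2)
  s <- 0
  for (n in 0:40) {
    s <- s + (-1)^n * x^(2 * n + 1) / (factorial(n) * (2 * n + 1))
  }
  0.5 + s / sqrt(pi)
}

# Irregular high-amplitude artifact burst spanning roughly [t0, t0+10] s.
burst_artifacts <- function(t0) {
  list(c(t0 + 0.2, 0.5, 12), c(t0 + 1.4, 0.9, -9), c(t0 + 2.1, 0.4, 15),
       c(t0 + 3.8, 1.1, -11), c(t0 + 4.6, 0.3, 9), c(t0 + 5.7, 0.8, -14),
       c(t0 + 7.2, 0.6, 10), c(t0 + 8.5, 1.2, -8), c(t0 + 9.3, 0.4, 13))
}

# Band-pass + demean convenience mirroring the pipeline's pre-processing.
filtered_channel <- function(rec, channel = "ir", fspec = filter_spec()) {
  fspec$rate_hz <- rec$rate_hz
  h <- design_fir(fspec)
  as.numeric(filter_signal(rec[[channel]] - mean(rec[[channel]]), h))
}
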