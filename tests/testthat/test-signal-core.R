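test_that("biased autocorrelation matches the direct-summation oracle", {
  withr::with_seed(42, {
    cases <- list(
      sin(2 * pi * (1:500) / 37) + rnorm(500, 0, 0.3),
      rnorm(300),
      cumsum(rnorm(400))
    )
  })
  for (x in cases) {
    r <- biased_autocorrelation(x, max_lag = 60)
    expect_equal(r$values[1], 1.0)
    expect_lte(max(abs(r$values)), 1 + 1e-12)
    expect_equal(r$values, oracle_autocorr(x, 60), tolerance = 1e-10)
  }
  expect_error(biased_autocorrelation(rep(3, 100), 10), "zero variance")
  expect_error(biased_autocorrelation(1:5, 10), "too short")
})

test_that("sine autocorrelation at one period follows the biased closed form", {
  x <- sin(2 * pi * (1:5000) / 50)
  r <- biased_autocorrelation(x, max_lag = 60)
  # biased estimator tapers by (1 - k/T) at a full-period lag
  expect_lt(abs(r$values[51] - (1 - 50 / 5000)), 0.02)
  expect_equal(r$values, oracle_autocorr(x, 60), tolerance = 1e-10)
})

test_that("white noise shows no spurious periodicity structure", {
  x <- withr::with_seed(99, rnorm(5000))
  r <- biased_autocorrelation(x, max_lag = 200)
  expect_lt(max(abs(r$values[-1])), 0.1)
})

test_that("beat period estimation recovers simulated heart rates", {
  for (hr in c(60, 120)) {
    rec <- simulate_recording(sim_config(duration_s = 60, hr_bpm = hr,
                                         seed = 8))$recording
    f <- filtered_channel(rec)
    p <- estimate_beat_period(f[500:2500], rec$rate_hz)
    expect_lte(abs(p - 60 * 50 / hr), 1)
  }
  noise <- withr::with_seed(13, rnorm(2000))
  expect_error(estimate_beat_period(noise, 50), "no beat")
})

test_that("periodicity score is high for clean PPG and degrades with noise", {
  clean <- sim_config(duration_s = 180, hr_jitter_pct = 0,
                      noise_sd_frac = 0, resp_amp_frac = 0, seed = 2)
  f <- filtered_channel(simulate_recording(clean)$recording)
  ps <- periodicity_score(f[500:8500], 50)
  expect_gte(ps$score, 0.95)
  expect_identical(ps$beat_period_samples, 50L)
  # additive noise at SD equal to the pulse amplitude strictly lowers it
  noisy_cfg <- sim_config(duration_s = 180, hr_jitter_pct = 0,
                          noise_sd_frac = 1, resp_amp_frac = 0, seed = 2)
  fn <- filtered_channel(simulate_recording(noisy_cfg)$recording)
  expect_lt(periodicity_score(fn[500:8500], 50)$score, ps$score)
  expect_error(periodicity_score(rep(1, 1000), 50), "zero variance")
})

test_that("Bessel I0 series matches independent oracles", {
  expect_identical(bessel_i0(0), 1.0)
  z <- c(0.3, 1, 2.5, 8)
  expect_equal(bessel_i0(-z), bessel_i0(z))
  for (zz in z) {
    expect_equal(bessel_i0(zz), oracle_bessel_i0(zz), tolerance = 1e-12)
  }
  # base R provides the same special function: cross-check
  expect_equal(bessel_i0(z), besselI(z, 0), tolerance = 1e-12)
  expect_error(bessel_i0(Inf), "finite")
})

test_that("Kaiser window follows its defining formula", {
  for (N in c(21, 500)) {
    w <- kaiser_window(N, 8)
    expect_length(w, N)
    expect_true(all(w > 0 & w <= 1))
    if (N %% 2 == 1) expect_equal(w[(N - 1) / 2 + 1], 1.0)
    expect_equal(w[1], 1 / oracle_bessel_i0(8), tolerance = 1e-9)
    expect_equal(w[N], 1 / oracle_bessel_i0(8), tolerance = 1e-9)
    expect_equal(w, rev(w))
    # unimodal: non-decreasing to the center, non-increasing after
    mid <- ceiling(N / 2)
    expect_true(all(diff(w[1:mid]) >= 0))
    expect_true(all(diff(w[mid:N]) <= 0))
  }
  if (requireNamespace("signal", quietly = TRUE)) {
    expect_equal(kaiser_window(101, 8), signal::kaiser(101, 8),
                 tolerance = 1e-12)
  }
})

test_that("FIR design gives a linear-phase band-pass with unit passband gain", {
  spec <- filter_spec()
  h <- design_fir(spec)
  expect_length(h, 500)
  expect_lt(abs(sum(h)), 1e-3)                       # DC in the stopband
  expect_equal(h, rev(h), tolerance = 1e-15)          # linear phase
  center <- (spec$band_low_hz + spec$band_high_hz) / 2
  expect_equal(oracle_dtft_gain(h, center, 50), 1, tolerance = 0.01)
  expect_error(filter_spec(band_low_hz = 5, band_high_hz = 30), "Nyquist")
  expect_error(filter_spec(band_low_hz = 8, band_high_hz = 2), "band edges")
})

test_that("filtering preserves passband tones, kills stopband tones, is aligned", {
  h <- design_fir(filter_spec())
  t <- (0:4999) / 50
  inb <- sin(2 * pi * 3 * t)
  y <- as.numeric(filter_signal(inb, h))
  ss <- 1000:4000
  expect_equal(max(abs(y[ss])), 1, tolerance = 0.01)
  # time alignment: with an odd tap count the group delay is integer, so
  # the compensated output is exactly in phase (even N leaves a half-sample)
  h_odd <- design_fir(filter_spec(length_N = 501))
  y_odd <- as.numeric(filter_signal(inb, h_odd))
  expect_gt(cor(y_odd[ss], inb[ss]), 0.9999)
  out <- sin(2 * pi * 20 * t)
  y2 <- as.numeric(filter_signal(out, h))
  expect_lt(max(abs(y2[ss])), 10^(-40 / 20))
  expect_identical(as.numeric(filter_signal(numeric(600), h)), numeric(600))
  expect_identical(attr(filter_signal(numeric(600), h), "transient_samples"),
                   250L)
  expect_error(filter_signal(numeric(100), h), "longer than the filter")
})

test_that("analytic envelope recovers constant and AM modulators", {
  t <- (0:2999) / 50
  tone <- 3 * cos(2 * pi * 2 * t)
  env <- analytic_envelope(tone)
  core <- 150:2850
  expect_lt(max(abs(env[core] - 3)) / 3, 0.01)
  expect_identical(analytic_envelope(numeric(64)), numeric(64))
  # AM signal: envelope must match the closed-form modulator
  mod <- 1 + 0.5 * cos(2 * pi * 0.1 * t)
  am <- mod * cos(2 * pi * 2 * t)
  env_am <- analytic_envelope(am)
  rms_err <- sqrt(mean((env_am[core] - mod[core])^2)) /
    sqrt(mean(mod[core]^2))
  expect_lt(rms_err, 0.01)
  # FFT and FIR-Hilbert variants agree away from the edges
  env_fir <- analytic_envelope(am, method = "fir")
  rel <- sqrt(mean((env_am[core] - env_fir[core])^2)) /
    sqrt(mean(env_am[core]^2))
  expect_lt(rel, 0.01)
  expect_error(analytic_envelope(1:3), "at least 4")
})

test_that("analytic envelope bounds the signal magnitude", {
  withr::with_seed(7, {
    for (trial in 1:5) {
      t <- (0:1999) / 50
      f <- runif(1, 1, 6)
      x <- cos(2 * pi * f * t) + 0.3 * cos(2 * pi * (f + 1.3) * t)
      env <- analytic_envelope(x)
      core <- 100:1900
      expect_true(all(env[core] >= abs(x[core]) - 1e-8))
    }
  })
})

test_that("running mean matches the cumulative-sum definition and edges shrink", {
  x <- withr::with_seed(5, rnorm(10000))
  rm60 <- running_mean(x, 60, 50)
  expect_identical(attr(rm60, "window_samples"), 3000L)
  expect_length(rm60, length(x))
  expect_equal(as.numeric(rm60), oracle_running_mean(x, 3000),
               tolerance = 1e-12)
  expect_equal(as.numeric(running_mean(rep(4.2, 500), 2, 50)), rep(4.2, 500))
  # unit step at the midpoint averages to ~0.5 at the step index
  step <- c(rep(0, 500), rep(1, 500))
  rs <- running_mean(step, 2, 50)
  expect_lt(abs(rs[500] - 0.5), 1 / 100 + 1e-9)
  expect_error(running_mean(numeric(0), 1, 50), "empty")
})
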