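test_that("beat detection finds one peak per cardiac cycle", {
  rec <- simulate_recording(sim_config(duration_s = 300, hr_bpm = 60,
                                       seed = 2))$recording
  f <- filtered_channel(rec, "red")
  beats <- detect_beats(f, rec$rate_hz)
  expect_lte(abs(length(beats$peak_indices) - 300), 2)
  expect_true(all(diff(beats$peak_indices) > 0))
  expect_true(all(beats$accepted))
  expect_warning(empty <- detect_beats(numeric(1000), 50), "no beats")
  expect_length(empty$peak_indices, 0)
})

test_that("a single motion transient barely perturbs the beat count", {
  base <- sim_config(duration_s = 300, hr_bpm = 60, seed = 2)
  with_art <- sim_config(duration_s = 300, hr_bpm = 60, seed = 2,
                         artifact_schedule = list(c(150, 0.8, 8)))
  n0 <- length(detect_beats(
    filtered_channel(simulate_recording(base)$recording, "red"), 50)$peak_indices)
  n1 <- length(detect_beats(
    filtered_channel(simulate_recording(with_art)$recording, "red"), 50)$peak_indices)
  expect_lte(abs(n1 - n0), 2)
})

test_that("periodicity gating rejects beats inside an artifact burst only", {
  rec <- simulate_recording(sim_config(
    duration_s = 180, seed = 4,
    artifact_schedule = burst_artifacts(90)))$recording
  f <- filtered_channel(rec)
  beats <- reject_noisy_beats(f, detect_beats(f, 50), detect_config())
  tt <- (beats$peak_indices - 1) / 50
  in_burst <- tt >= 90 & tt <= 100
  expect_gt(sum(in_burst), 0)
  expect_true(all(!beats$accepted[in_burst]))
  # beats more than one assessment window away from the burst all survive
  far <- tt < 80 | tt > 110
  expect_true(all(beats$accepted[far]))
})

test_that("clean recordings keep all beats; threshold zero is vacuous", {
  rec <- simulate_recording(sim_config(duration_s = 180, noise_sd_frac = 0,
                                       seed = 6))$recording
  f <- filtered_channel(rec)
  beats <- detect_beats(f, 50)
  gated <- reject_noisy_beats(f, beats, detect_config())
  expect_true(all(gated$accepted))
  expect_s3_class(gated$window_scores, "data.frame")
  # noisy recording but vacuous threshold: everything accepted
  nrec <- simulate_recording(sim_config(duration_s = 120, noise_sd_frac = 1,
                                        seed = 6))$recording
  nf <- filtered_channel(nrec)
  nb <- detect_beats(nf, 50)
  vac <- reject_noisy_beats(nf, nb, detect_config(periodicity_threshold = 0))
  expect_true(all(vac$accepted))
})

test_that("percent vasoconstriction follows its defining ratio", {
  env <- structure(list(values = rep(10, 100), smoothed = rep(10, 100),
                        baseline = rep(10, 100), rate_hz = 50),
                   class = "envelope_series")
  expect_equal(percent_vasoconstriction(env, 50)$percent, 0)
  env$smoothed[60] <- 7   # minimum at 0.70 x baseline
  pv <- percent_vasoconstriction(env, 60)
  expect_equal(pv$percent, 30)
  expect_equal(pv$ratio, 0.7)
  env$baseline[70] <- 0
  expect_error(percent_vasoconstriction(env, 70), "baseline is zero")
  expect_error(percent_vasoconstriction(env, 200), "out of range")
})

test_that("simulated constriction depth is recovered within 3 points", {
  sim <- simulate_recording(sim_config(
    duration_s = 300, seed = 21,
    event_schedule = list(vaso_event_spec(150, 25))))
  an <- process_recording(sim$recording)
  expect_identical(nrow(an$events), 1L)
  expect_lt(abs(an$events$percent - 25), 3)
})

test_that("percent vasoconstriction is invariant to uniform rescaling", {
  cfg <- sim_config(duration_s = 200, seed = 9,
                    event_schedule = list(vaso_event_spec(100, 30)))
  rec <- simulate_recording(cfg, quantize = FALSE)$recording
  f <- filtered_channel(rec)
  for (scale in c(1, 3.7)) {
    env <- envelope_series(f * scale, 50)
    pv <- percent_vasoconstriction(env, which.min(env$smoothed / env$baseline))
    if (scale == 1) p_ref <- pv$percent else {
      expect_equal(pv$percent, p_ref, tolerance = 1e-9)
    }
  }
})

test_that("event segmentation finds programmed events and nothing else", {
  # no programmed events, low noise -> empty
  null_an <- process_recording(simulate_recording(
    sim_config(duration_s = 300, seed = 31, noise_sd_frac = 0.02))$recording)
  expect_identical(nrow(null_an$events), 0L)
  # one 30% event -> one event at the programmed nadir
  sim1 <- simulate_recording(sim_config(
    duration_s = 300, seed = 32,
    event_schedule = list(vaso_event_spec(120, 30))))
  an1 <- process_recording(sim1$recording)
  expect_identical(nrow(an1$events), 1L)
  expect_lte(abs(an1$events$nadir_s - sim1$truth$events$nadir_s), 2)
  expect_true(an1$events$onset_s <= an1$events$nadir_s)
  expect_true(an1$events$nadir_s <= an1$events$end_s)
  # two events 60 s apart -> two events in order
  sim2 <- simulate_recording(sim_config(
    duration_s = 300, seed = 33,
    event_schedule = list(vaso_event_spec(100, 20),
                          vaso_event_spec(160, 35))))
  an2 <- process_recording(sim2$recording)
  expect_identical(nrow(an2$events), 2L)
  expect_true(all(diff(an2$events$nadir_s) > 0))
  expect_lt(abs(an2$events$nadir_s[1] - sim2$truth$events$nadir_s[1]), 4)
  expect_lt(abs(an2$events$nadir_s[2] - sim2$truth$events$nadir_s[2]), 4)
})

test_that("detected events never exceed programmed events plus artifacts", {
  for (seed in 41:45) {
    cfg <- sim_config(
      duration_s = 300, seed = seed,
      event_schedule = list(vaso_event_spec(80, 15), vaso_event_spec(200, 35)),
      artifact_schedule = list(c(140, 0.8, 8)))
    an <- process_recording(simulate_recording(cfg)$recording)
    expect_lte(nrow(an$events), 2 + 1)
  }
})

test_that("size bins follow the small/medium/large schema", {
  b <- classify_event(c(10, 20, 40))
  expect_identical(as.character(b), c("small", "medium", "large"))
  # half-open boundaries
  expect_identical(as.character(classify_event(c(15, 30))),
                   c("medium", "large"))
  expect_identical(as.character(classify_event(0)), "small")
  over <- classify_event(55)
  expect_identical(as.character(over), "large")
  expect_true(attr(over, "out_of_range"))
  expect_false(any(attr(classify_event(c(10, 49)), "out_of_range")))
  expect_error(classify_event(-2), "non-negative")
})

test_that("trial tallies report integer detection percentages", {
  s <- trial_detection_summary(c(rep(1, 41), rep(0, 4)))
  expect_identical(s$detected, 41L)
  expect_identical(s$percent, 91L)
  expect_identical(trial_detection_summary(c(2, 0, 1))$percent, 67L)
  expect_error(trial_detection_summary(integer(0)), "no trials")
})
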