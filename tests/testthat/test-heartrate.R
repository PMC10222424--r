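# Beat detection, heart-rate curves, correlation metrics, SNR estimation,
# signal-quality screening.

test_that("clean beats are located within 20 ms of the truth", {
  rr <- generate_rr_sequence(70, 0.03, 10, seed = 21)
  sig <- render_ecg(rr, beat_morphology("pqrst"))
  train <- detect_beats(sig)
  truth <- attr(sig, "beat_times")
  expect_equal(length(train$peak_times), length(truth))
  expect_lt(max(abs(train$peak_times - truth)), 0.020)
  # the wave-like channel yields one detection per cycle as well
  wv <- render_ecg(rr, beat_morphology("single_position_wave"))
  expect_equal(length(detect_beats(wv)$peak_times), length(truth))
})

test_that("an empty signal yields an empty train with a warning flag", {
  z <- ecg_signal(numeric(5000), T = 1 / 500, provenance = "clean")
  expect_warning(train <- detect_beats(z), "no beats")
  expect_length(train$peak_times, 0)
  expect_true(train$warning_flag)
  expect_error(detect_beats(sine_signal(10, duration_s = 2)), "5 s")
})

test_that("detection is invariant to gain and offset", {
  rr <- generate_rr_sequence(70, 0.03, 60, seed = 22)
  sig <- add_noise(render_ecg(rr, beat_morphology("pqrst"), duration_s = 45),
                   white_only_preset(20), seed = 5)
  base <- detect_beats(sig)$peak_times
  for (tf in list(function(x) 0.1 * x, function(x) 10 * x,
                  function(x) x + 2.5)) {
    mod <- ecg_signal(tf(sig$samples), T = sig$T, provenance = "noisy")
    expect_equal(detect_beats(mod)$peak_times, base)
  }
})

test_that("the refractory period is respected", {
  rr <- generate_rr_sequence(70, 0.03, 60, seed = 23)
  sig <- add_noise(render_ecg(rr, beat_morphology("pqrst"), duration_s = 45),
                   white_only_preset(12), seed = 6)
  train <- detect_beats(sig)
  expect_true(all(diff(train$peak_times) >= 0.2))
})

test_that("the heart-rate formula and validity filter are applied", {
  # n * T = 1 s -> 60 bpm; n = 160 samples at T = 1/200 s -> 75 bpm
  tr <- structure(list(peak_times = c(1, 2, 2.8), n = c(200, 160),
                       T = 1 / 200, warning_flag = FALSE),
                  class = "peak_train")
  hr <- compute_heart_rate_curve(tr)
  expect_equal(hr$fhr_bpm, c(60, 75))
  expect_equal(hr$times, c(2, 2.8))
  # constant rhythm gives a flat curve
  rr <- generate_rr_sequence(75, 0, 120, seed = 1)
  sig <- render_ecg(rr, beat_morphology("pqrst"), duration_s = 90)
  hr2 <- compute_heart_rate_curve(detect_beats(sig))
  expect_lt(max(hr2$fhr_bpm) - min(hr2$fhr_bpm), 0.1)
  expect_error(compute_heart_rate_curve(
    structure(list(peak_times = 1, n = numeric(0), T = 1 / 200,
                   warning_flag = FALSE), class = "peak_train")),
    "two peaks")
})

test_that("correlation and extremum deviation behave on known pairs", {
  tt <- 0:299
  a <- structure(list(times = tt, fhr_bpm = 70 + 5 * sin(tt / 20)),
                 class = "heart_rate_curve")
  expect_equal(correlate_heart_rate(a, a), 1)
  b <- a; b$fhr_bpm <- 140 - a$fhr_bpm
  expect_equal(correlate_heart_rate(a, b), -1)
  expect_equal(unname(extremum_deviation(a, a)), c(0, 0))
  shifted <- a; shifted$fhr_bpm <- a$fhr_bpm + 2
  expect_equal(unname(extremum_deviation(a, shifted)), c(2, 2))
  flat <- a; flat$fhr_bpm <- rep(70, 300)
  expect_error(correlate_heart_rate(a, flat), "zero variance")
  short_a <- a; short_a$times <- tt[1:30]; short_a$fhr_bpm <- a$fhr_bpm[1:30]
  expect_warning(correlate_heart_rate(short_a, short_a), "60 s")
})

test_that("clean pipelines recover the generated rhythm within 1 bpm", {
  rr <- generate_rr_sequence(70, 0.05, 150, seed = 24)
  sig <- render_ecg(rr, beat_morphology("pqrst"), duration_s = 110)
  hr <- compute_heart_rate_curve(detect_beats(sig))
  truth_t <- attr(sig, "beat_times")[-1]
  truth_hr <- 60 / diff(attr(sig, "beat_times"))
  matched <- approx(truth_t, truth_hr, hr$times, rule = 2)$y
  expect_lt(max(abs(hr$fhr_bpm - matched)), 1)
})

test_that("the SNR estimator tracks ground truth and saturates when clean", {
  chain <- design_filter_chain(filter_chain_spec(0.5), 500)
  est_at <- function(snr_db, seed) {
    rr <- generate_rr_sequence(70, 0.03, 150, seed = seed)
    clean <- render_ecg(rr, beat_morphology("pqrst"), duration_s = 120)
    noisy <- add_noise(clean, white_only_preset(snr_db), seed = seed + 50)
    train <- detect_beats(apply_filter_chain(chain, noisy))
    estimate_snr(noisy, train)
  }
  expect_lt(abs(est_at(20, 31) - 20), 3)
  expect_lt(abs(est_at(12, 32) - 12), 3)
  # identical noiseless beats leave essentially no residual
  rr0 <- generate_rr_sequence(75, 0, 150, seed = 33)
  clean0 <- render_ecg(rr0, beat_morphology("pqrst"), duration_s = 110)
  expect_gt(estimate_snr(clean0, detect_beats(clean0)), 40)
  few <- detect_beats(clean0)
  few$peak_times <- few$peak_times[1:5]
  expect_error(estimate_snr(clean0, few), "10 beats")
})

test_that("the unrecognizable-signal rules flag corrupted windows", {
  rr <- generate_rr_sequence(70, 0.03, 150, seed = 25)
  clean <- render_ecg(rr, beat_morphology("pqrst"), duration_s = 100)
  expect_equal(unrecognizable_fraction(clean), 0)
  # two of ten windows swamped by high-amplitude noise
  corrupted <- clean$samples
  set.seed(26)
  corrupted[10001:15000] <- rnorm(5000, sd = 20)
  corrupted[35001:40000] <- rnorm(5000, sd = 20)
  bad2 <- ecg_signal(corrupted, T = clean$T, provenance = "noisy")
  expect_equal(unrecognizable_fraction(bad2), 0.2)
  # pure noise is fully unrecognizable
  set.seed(27)
  noise <- ecg_signal(rnorm(50000), T = 1 / 500, provenance = "noisy")
  expect_equal(unrecognizable_fraction(noise), 1)
  expect_error(unrecognizable_fraction(
    ecg_signal(clean$samples[1:5000], T = clean$T, provenance = "clean")),
    "three windows")
})

test_that("correlation degrades on average as the SNR drops", {
  chain <- design_filter_chain(filter_chain_spec(0.5), 500)
  r_at <- function(snr_db, seed) {
    rr <- generate_rr_sequence(70, 0.03, 140, seed = seed)
    pair <- make_paired_recording(rr, exp_preset = white_only_preset(snr_db),
                                  ctrl_preset = white_only_preset(snr_db),
                                  seed = seed, duration_s = 90)
    he <- compute_heart_rate_curve(detect_beats(
      apply_filter_chain(chain, pair$experimental)))
    hc <- compute_heart_rate_curve(detect_beats(
      apply_filter_chain(chain, pair$control)))
    tryCatch(suppressWarnings(correlate_heart_rate(he, hc)),
             error = function(e) 0)
  }
  seeds <- 1:20
  r20 <- mean(vapply(seeds, function(s) r_at(20, s), numeric(1)))
  r12 <- mean(vapply(seeds, function(s) r_at(12, s), numeric(1)))
  r6  <- mean(vapply(seeds, function(s) r_at(6, s),  numeric(1)))
  expect_gt(r20, r12)
  expect_gt(r12, r6)
})
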