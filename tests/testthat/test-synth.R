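# Synthetic paired recordings: RR generation, morphologies, noise model.

test_that("RR generation honours its distribution and its seed", {
  # zero variance collapses to the exact mean interval
  rr0 <- generate_rr_sequence(60, 0, 10, seed = 5)
  expect_equal(rr0$intervals, rep(1.0, 10))
  # seeding contract
  a <- generate_rr_sequence(75, 0.02, 400, seed = 1)
  b <- generate_rr_sequence(75, 0.02, 400, seed = 1)
  expect_identical(a$intervals, b$intervals)
  expect_false(identical(
    a$intervals, generate_rr_sequence(75, 0.02, 400, seed = 2)$intervals))
  # mean rate within 3 standard errors of the target
  # (rate = 60/interval; delta method: se ~ 75^2/60 * sdnn / sqrt(n))
  rate <- mean(60 / a$intervals)
  se <- 75^2 / 60 * 0.02 / sqrt(400)
  expect_lt(abs(rate - 75), 3 * se)
  expect_error(generate_rr_sequence(10, 0.02, 10), "mean_bpm")
  expect_error(generate_rr_sequence(70, -1, 10), "sdnn")
})

test_that("PQRST rendering places one dominant peak per beat", {
  rr <- generate_rr_sequence(70, 0.02, 10, seed = 3)
  sig <- render_ecg(rr, beat_morphology("pqrst"))
  x <- sig$samples
  peaks <- which(diff(sign(diff(x))) < 0) + 1L
  big <- peaks[x[peaks] > 0.5 * max(x)]
  expect_equal(length(big), 10)
  expect_equal(length(attr(sig, "beat_times")), 10)
})

test_that("clean PQRST energy is concentrated in the ECG band", {
  rr <- generate_rr_sequence(70, 0.03, 120, seed = 4)
  sig <- render_ecg(rr, beat_morphology("pqrst"), duration_s = 60)
  expect_gte(band_energy_fraction(sig, 0.25, 35), 0.90)
})

test_that("both morphologies carry the same cycle length", {
  # constant rhythm; the cycle shows up as the first autocorrelation peak
  rr <- generate_rr_sequence(75, 0, 60, seed = 1)
  fs <- 500
  lag_of <- function(sig) {
    x <- sig$samples - mean(sig$samples)
    ac <- stats::acf(x, lag.max = round(1.5 * fs), plot = FALSE)$acf
    from <- round(0.4 * fs)
    from - 1 + which.max(ac[from:length(ac)])
  }
  pq <- render_ecg(rr, beat_morphology("pqrst"), fs, duration_s = 40)
  wv <- render_ecg(rr, beat_morphology("single_position_wave"), fs,
                   duration_s = 40)
  expect_lte(abs(lag_of(pq) - lag_of(wv)), 1)
})

test_that("the wave morphology is visibly smaller than PQRST", {
  rr <- generate_rr_sequence(70, 0.02, 30, seed = 2)
  pq <- render_ecg(rr, beat_morphology("pqrst"))
  wv <- render_ecg(rr, beat_morphology("single_position_wave"))
  expect_lt(diff(range(wv$samples)), diff(range(pq$samples)))
})

test_that("noise injection hits the target SNR exactly", {
  rr <- generate_rr_sequence(70, 0.03, 80, seed = 6)
  sig <- render_ecg(rr, beat_morphology("pqrst"), duration_s = 60)
  for (nm in c("sitting", "stepping")) {
    noisy <- add_noise(sig, nm, seed = 9)
    truth <- attr(noisy, "noise_truth")
    target <- noise_preset(nm)$snr_db
    expect_equal(truth$snr_db, target, tolerance = 0.1 / target)
    realized <- 10 * log10(truth$signal_power / truth$white_power)
    expect_equal(realized, target, tolerance = 1e-9)
  }
  # the all-zero preset is the identity
  same <- add_noise(sig, "clean", seed = 9)
  expect_identical(same$samples, sig$samples)
})

test_that("preset levels match the measurement postures", {
  expect_gte(noise_preset("sitting")$snr_db, 20)
  for (nm in c("office", "turning", "stepping"))
    expect_equal(noise_preset(nm)$snr_db, 12)
  expect_lt(noise_preset("low_drift")$drift_sd,
            noise_preset("sitting")$drift_sd)
})

test_that("drift stays below 0.5 Hz and powerline sits at 50 Hz", {
  rr <- generate_rr_sequence(70, 0, 80, seed = 2)
  quiet <- render_ecg(rr, beat_morphology("pqrst"), duration_s = 60)
  base <- quiet$samples
  noisy <- add_noise(quiet, "stepping", seed = 4)
  added <- noisy$samples - base
  resid <- ecg_signal(added, T = noisy$T, provenance = "noisy")
  # drift is strong and sub-hertz; the powerline line is at exactly 50 Hz
  expect_gt(band_energy_fraction(resid, 0.001, 0.5), 0.5)
  w <- welch_psd(resid$samples, 500)
  line <- w$freq[w$freq > 5][which.max(w$psd[w$freq > 5])]
  expect_equal(line, 50, tolerance = 0.01)
})

test_that("paired recordings share the rhythm but not the noise", {
  rr <- generate_rr_sequence(70, 0.03, 120, seed = 8)
  pair <- make_paired_recording(rr, duration_s = 60, seed = 1)
  expect_equal(length(pair$experimental$samples), 60 * 500)
  expect_equal(length(pair$control$samples), 60 * 500)
  expect_identical(attr(pair$experimental, "beat_times"),
                   attr(pair$control, "beat_times"))
  pair2 <- make_paired_recording(rr, duration_s = 60, seed = 2)
  expect_identical(pair2$truth$intervals, pair$truth$intervals)
  expect_false(identical(pair2$experimental$samples,
                         pair$experimental$samples))
  # too-short RR sequences are refused
  short <- generate_rr_sequence(70, 0.03, 10, seed = 1)
  expect_error(make_paired_recording(short, duration_s = 60), "shorter")
})

test_that("the dynamic recording switches posture every segment", {
  rr <- generate_rr_sequence(70, 0.03, 300, seed = 9)
  dyn <- synthesize_dynamic_recording(rr, seed = 3, segment_s = 60)
  seg <- attr(dyn, "segments")
  expect_equal(seg$posture, c("sitting", "office", "turning", "stepping"))
  expect_equal(seg$start_s, c(0, 60, 120, 180))
  expect_equal(length(dyn$samples), 4 * 60 * 500)
  truth <- attr(dyn, "noise_truth")
  expect_equal(10 * log10(truth$sitting$signal_power /
                            truth$sitting$white_power), 20, tolerance = 1e-9)
  expect_equal(10 * log10(truth$stepping$signal_power /
                            truth$stepping$white_power), 12, tolerance = 1e-9)
})
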