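# Whole-phantom runs: activation sequence, conduction block, surface leads.

test_that("excitation follows the conduction system in order", {
  rec <- test_recording()
  act <- rec$activation_times[active_regions()]
  expect_false(anyNA(act))
  expect_true(all(diff(act) > 0))
  expect_false(rec$propagation_failure)
})

test_that("every stimulus yields one ventricular activation", {
  rec <- test_recording()
  expect_equal(count_activations(rec, "ventricles"), rec$stimulus_count)
  expect_equal(count_activations(rec, "sinoatrial_node"), rec$stimulus_count)
})

test_that("without a stimulus all traces stay at rest", {
  ph <- test_phantom()
  quiet <- stimulus_protocol(amplitude = 0)
  rec <- run_simulation(ph, quiet, duration_s = 1.8)
  for (tr in rec$traces) expect_equal(max(abs(tr)), 0)
  expect_true(all(is.na(rec$activation_times)))
})

test_that("blocking the AV node stops ventricular activation", {
  ph <- test_phantom()
  lab <- ph$labels
  lab[lab == region_id("atrioventricular_node")] <- region_id("fibrous_barrier")
  blocked <- phantom_from_labels(lab, ph$spacing, ph$params)
  expect_warning(
    rec <- run_simulation(blocked, stimulus_protocol(), duration_s = 1.8),
    "propagation failure")
  expect_true(rec$propagation_failure)
  expect_equal(count_activations(rec, "ventricles"), 0)
  expect_lt(max(rec$region_means[, "ventricles"]), 0.05)
  # the atrial rhythm continues
  expect_gt(count_activations(rec, "atria"), 0)
})

test_that("passive regions never exceed cardiac amplitudes", {
  rec <- test_recording()
  cardiac <- max(rec$region_max[, active_regions()])
  passive <- max(rec$region_max[, passive_regions()])
  expect_lt(passive, cardiac)
})

test_that("simulation is deterministic", {
  cfg <- test_config()
  ph <- uniecg:::config_phantom(cfg)
  r1 <- run_simulation(ph, stimulus_protocol(), duration_s = 1.7)
  r2 <- run_simulation(ph, stimulus_protocol(), duration_s = 1.7)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$region_means, r2$region_means)
})

test_that("the conventional lead shows P-, QRS- and T-like deflections", {
  rec <- test_recording()
  lead <- extract_conventional_lead(rec)
  fs <- 1 / lead$T
  # second beat, away from the onset transient
  seg <- lead$samples[(round(0.8 * fs) + 1):round(1.6 * fs)]
  seg <- seg - mean(seg)
  ext <- which(diff(sign(diff(seg))) != 0) + 1L
  ext <- ext[abs(seg[ext]) > 0.15 * max(abs(seg))]
  # cluster extrema closer than 35 ms into single deflections
  defl_t <- (ext[c(TRUE, diff(ext) > 0.035 * fs)] - 1) / fs
  expect_gte(length(defl_t), 3)
})

test_that("the single-position trace is smoother than the conventional lead", {
  rec <- test_recording()
  conv <- extract_conventional_lead(rec)
  single <- extract_single_position(rec)
  hf <- function(s) {
    X <- Mod(fft(s$samples - mean(s$samples)))^2
    n <- length(s$samples)
    f <- (seq_len(n) - 1) / (n * s$T)
    half <- 2:floor(n / 2)
    sum(X[half][f[half] > 10]) / sum(X[half])
  }
  expect_lt(hf(single), 0.5 * hf(conv))
})

test_that("both detection modes see the same rhythm", {
  rec <- test_recording()
  conv <- extract_conventional_lead(rec)
  single <- extract_single_position(rec)
  # one marker per stimulus cycle: the in-window peak time
  cyc <- function(s) {
    fs <- 1 / s$T
    vapply(0:2, function(b) {
      w <- (round(b * 0.8 * fs) + 1):round((b + 1) * 0.8 * fs)
      (w[which.max(s$samples[w])] - 1) / fs
    }, numeric(1))
  }
  a <- cyc(conv); b <- cyc(single)
  expect_equal(length(a), length(b))
  expect_gt(cor(a, b), 0.999)
})

test_that("lead extraction validates probe names and cancels common signal", {
  rec <- test_recording()
  expect_error(extract_conventional_lead(rec, "nope"), "no conventional probe")
  expect_error(extract_single_position(rec, "nope"), "no single-position probe")
  fake <- rec
  fake$traces[["conventional.ref"]] <- fake$traces[["conventional.det"]]
  expect_equal(max(abs(extract_conventional_lead(fake)$samples)), 0)
  # a constant offset between the electrodes is removed by mean removal
  fake$traces[["conventional.ref"]] <- fake$traces[["conventional.det"]] + 3
  expect_equal(max(abs(extract_conventional_lead(fake)$samples)), 0,
               tolerance = 1e-12)
})

test_that("single-position probes require the electrode layer", {
  cfg <- test_config()
  cfg$phantom$include_electrode_layer <- FALSE
  ph <- uniecg:::config_phantom(cfg)
  bad <- probe_spec("single_position", c(2, 3))
  expect_error(
    run_simulation(ph, stimulus_protocol(), probes = list(bad),
                   duration_s = 1.7),
    "electrode layer")
})

test_that("short runs are refused", {
  ph <- test_phantom()
  expect_error(run_simulation(ph, stimulus_protocol(), duration_s = 1.0),
               "two stimulus periods")
})
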