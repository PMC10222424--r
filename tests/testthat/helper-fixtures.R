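# Shared fixtures, built once per test run.

test_config <- function() {
  cfg <- default_run_config()
  cfg$phantom$rows <- 100L
  cfg$phantom$cols <- 100L
  cfg$simulation$duration_s <- 2.4
  cfg
}

test_phantom <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- uniecg:::config_phantom(test_config())
    val
  }
})

# one short default simulation (three beats at 100x100), reused widely
test_recording <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- test_config()
      val <<- run_simulation(test_phantom(), uniecg:::config_protocol(cfg),
                             duration_s = cfg$simulation$duration_s)
    }
    val
  }
})

# homogeneous strip phantom of one region, stimulated from the left edge
strip_state <- function(region, ncols = 240, nrows = 11) {
  lab <- matrix(region, nrows, ncols)
  ph <- phantom_from_labels(lab, spacing = 0.5)
  st <- field_state(ph)
  st$u1[, 1:4] <- 1
  list(phantom = ph, state = st)
}

# column reached by the excitation front along the middle row
front_column <- function(u1, threshold = 0.5) {
  w <- which(u1[ceiling(nrow(u1) / 2), ] > threshold)
  if (length(w)) max(w) else 0L
}

sine_signal <- function(freq_hz, duration_s = 30, fs = 500, amp = 1) {
  tt <- (seq_len(round(duration_s * fs)) - 1) / fs
  ecg_signal(amp * sin(2 * pi * freq_hz * tt), T = 1 / fs,
             provenance = "clean")
}

# fixed-variance white-noise corruption at an exact SNR, no drift/powerline
white_only_preset <- function(snr_db) {
  p <- noise_preset("clean")
  p$snr_db <- snr_db
  p
}
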