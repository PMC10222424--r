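# ECG filtering chains: high-pass -> powerline notches -> low-pass,
# applied forward-backward (zero phase) so R-peak timing is not distorted.

#' Specify an ECG filter chain
#'
#' The measurement protocol uses two arms: the one-electrode arm high-passes
#' at 0.5 Hz (the raw single-position signal is strongly drift-prone), the
#' modified-electrode arm at 0.25 Hz to retain more low-frequency ECG
#' energy. Both arms notch 50 Hz and 100 Hz and low-pass at 100 Hz.
#'
#' @param highpass_cutoff_hz High-pass cutoff (default 0.5).
#' @param notch_freqs_hz Notch frequencies (default 50 and 100 Hz).
#' @param lowpass_cutoff_hz Low-pass cutoff (default 100).
#' @param hp_order,lp_order Butterworth orders (default 4).
#' @param notch_q Notch quality factor (default 30).
#' @return A `filter_chain_spec`.
#' @export
filter_chain_spec <- function(highpass_cutoff_hz = 0.5,
                              notch_freqs_hz = c(50, 100),
                              lowpass_cutoff_hz = 100,
                              hp_order = 4, lp_order = 4, notch_q = 30) {
  if (highpass_cutoff_hz <= 0 || lowpass_cutoff_hz <= highpass_cutoff_hz)
    stop("need 0 < highpass < lowpass")
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 notch_freqs_hz = notch_freqs_hz,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 hp_order = hp_order, lp_order = lp_order,
                 notch_q = notch_q),
            class = "filter_chain_spec")
}

# RBJ biquad notch at f0 with quality q
notch_biquad <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  list(b = b / a[1], a = a / a[1])
}

#' Design a filter chain for a sampling rate
#'
#' Builds the cascade high-pass, notches, low-pass as Butterworth IIR
#' stages plus second-order notch biquads, and checks all corner
#' frequencies against the Nyquist limit.
#'
#' @param spec A [filter_chain_spec()].
#' @param fs Sampling rate in Hz.
#' @return A `filter_chain` whose magnitude response can be queried with
#'   [chain_response()] and applied with [apply_filter_chain()].
#' @export
design_filter_chain <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$lowpass_cutoff_hz >= nyq)
    stop("low-pass cutoff ", spec$lowpass_cutoff_hz,
         " Hz is at or above Nyquist (", nyq, " Hz)")
  if (any(spec$notch_freqs_hz >= nyq))
    stop("notch frequency at or above Nyquist (", nyq, " Hz)")
  hp <- signal::butter(spec$hp_order, spec$highpass_cutoff_hz / nyq,
                       type = "high")
  lp <- signal::butter(spec$lp_order, spec$lowpass_cutoff_hz / nyq,
                       type = "low")
  stages <- c(list(list(b = hp$b, a = hp$a)),
              lapply(spec$notch_freqs_hz, notch_biquad, q = spec$notch_q,
                     fs = fs),
              list(list(b = lp$b, a = lp$a)))
  structure(list(stages = stages, fs = fs, spec = spec),
            class = "filter_chain")
}

#' Magnitude response of a filter chain
#'
#' Single-pass magnitude of the cascade at the requested frequencies.
#' [apply_filter_chain()] runs the chain forward and backward, so the
#' applied attenuation is the square of this response (twice the decibels).
#'
#' @param chain A [design_filter_chain()] result.
#' @param freqs_hz Frequencies to evaluate.
#' @return Numeric vector of magnitudes (same length as `freqs_hz`).
#' @export
chain_response <- function(chain, freqs_hz) {
  z <- exp(-1i * 2 * pi * freqs_hz / chain$fs)
  H <- rep(1 + 0i, length(z))
  for (st in chain$stages) {
    num <- outer(z, seq_along(st$b) - 1, `^`) %*% st$b
    den <- outer(z, seq_along(st$a) - 1, `^`) %*% st$a
    H <- H * (num / den)
  }
  as.numeric(Mod(H))
}

# settling length of the slowest stage, in seconds
chain_transient_s <- function(chain) 2 / chain$spec$highpass_cutoff_hz

#' Apply a filter chain, zero phase
#'
#' Runs every stage forward-backward (`signal::filtfilt`), which preserves
#' length and peak timing. The signal must be at least three transients of
#' the slowest stage long.
#'
#' @param chain A [design_filter_chain()] result.
#' @param signal An [ecg_signal()] sampled at the chain's rate.
#' @return The filtered [ecg_signal()].
#' @export
apply_filter_chain <- function(chain, signal) {
  fs <- 1 / signal$T
  if (abs(fs - chain$fs) > 1e-6)
    stop("signal sampled at ", fs, " Hz but the chain was designed for ",
         chain$fs, " Hz")
  if (signal_duration(signal) <= 3 * chain_transient_s(chain))
    stop("signal too short to filter: need more than ",
         3 * chain_transient_s(chain), " s for the ",
         chain$spec$highpass_cutoff_hz, " Hz high-pass")
  x <- signal$samples
  for (st in chain$stages) x <- signal::filtfilt(st$b, st$a, x)
  out <- ecg_signal(x, T = signal$T, channel = signal$channel,
                    provenance = signal$provenance)
  attr(out, "beat_times") <- attr(signal, "beat_times")
  attr(out, "noise_truth") <- attr(signal, "noise_truth")
  attr(out, "segments") <- attr(signal, "segments")
  out
}

#' Welch power spectral density
#'
#' Hann-windowed segment-averaged periodogram with 50% overlap and
#' per-segment mean removal.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (default: 4096, shortened to fit).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = 4096) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(fft(seg))^2
  }
  acc <- acc / (length(starts) * sum(win^2) * fs)
  half <- seq_len(nperseg %/% 2L + 1L)
  psd <- acc[half]
  # fold the negative frequencies into the one-sided density
  inner <- 2:(length(half) - 1L)
  psd[inner] <- 2 * psd[inner]
  list(freq = (half - 1L) * fs / nperseg, psd = psd)
}

#' Fraction of spectral energy inside a band
#'
#' Welch-periodogram energy in `[f_lo, f_hi]` divided by the total energy
#' above DC.
#'
#' @param signal An [ecg_signal()].
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi <= fs/2`.
#' @param nperseg Welch segment length.
#' @return Fraction in `[0, 1]`.
#' @export
band_energy_fraction <- function(signal, f_lo, f_hi, nperseg = 4096) {
  if (length(signal$samples) == 0L) stop("empty signal")
  fs <- 1 / signal$T
  if (!(f_lo < f_hi) || f_hi > fs / 2)
    stop("need f_lo < f_hi <= fs/2")
  w <- welch_psd(signal$samples, fs, nperseg)
  keep <- w$freq > 0
  total <- sum(w$psd[keep])
  if (total == 0) stop("signal has no energy above DC")
  sum(w$psd[keep & w$freq >= f_lo & w$freq <= f_hi]) / total
}
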