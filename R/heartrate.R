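# Beat detection, heart-rate graphs and the correlation-based reliability
# evaluation comparing single-position and conventional channels.

# centered moving average, edges padded with the edge value
moving_avg <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  xp <- c(rep(x[1], w), x, rep(x[n], w))
  f <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))
  f[(w + 1L):(w + n)]
}

#' Detect beats in a filtered ECG signal
#'
#' Derivative-square-integrate detection with an adaptive threshold: the
#' trace is band-limited by a 30 ms moving average (a smoothed
#' differentiator, so wideband noise does not drown the slope of smooth
#' beat shapes), differentiated, squared and integrated over a 150 ms
#' moving window; candidate beats are maxima of the integrated energy
#' above a running-median + 3 MAD threshold (with a relative amplitude
#' gate, so detection is invariant to gain and DC offset); each candidate
#' is refined to the local maximum of the smoothed trace with parabolic
#' sub-sample interpolation, and a 200 ms refractory period is enforced.
#' Deterministic.
#'
#' @param signal A filtered [ecg_signal()] of at least 5 s.
#' @param refractory_s Minimum separation between beats (default 0.2 s).
#' @return A `peak_train`: list with `peak_indices` (integer samples),
#'   `peak_times` (seconds, sub-sample), `n` (inter-peak distances in
#'   samples), `T`, and `warning_flag` (`TRUE` when nothing was found).
#' @export
detect_beats <- function(signal, refractory_s = 0.2) {
  fs <- 1 / signal$T
  if (signal_duration(signal) < 5)
    stop("beat detection needs at least 5 s of signal")
  x <- signal$samples - mean(signal$samples)
  sm <- moving_avg(x, max(1L, round(0.03 * fs)))
  if (max(sm) < -min(sm)) { x <- -x; sm <- -sm }   # dominant-peak polarity
  d <- c(0, diff(sm)) * fs
  integ <- moving_avg(d^2, max(1L, round(0.15 * fs)))
  k <- round(2 * fs); if (k %% 2L == 0L) k <- k + 1L
  base <- runmed(integ, min(k, length(integ) - (1 - length(integ) %% 2L)))
  thr <- base + 3 * mad(integ)
  above <- integ > thr
  empty <- structure(list(peak_indices = integer(0), peak_times = numeric(0),
                          n = numeric(0), T = signal$T, warning_flag = TRUE),
                     class = "peak_train")
  if (!any(above)) {
    warning("no beats found")
    return(empty)
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- mapply(function(s, e) s - 1L + which.max(integ[s:e]),
                 starts[runs$values], ends[runs$values])
  heights <- integ[cand]
  cand <- cand[heights >= 0.2 * quantile(heights, 0.95)]
  if (!length(cand)) {
    warning("no beats found")
    return(empty)
  }
  # refine on the smoothed trace with a parabolic vertex
  half <- round(0.15 * fs)
  n <- length(x)
  ref_idx <- numeric(length(cand)); ref_amp <- numeric(length(cand))
  for (q in seq_along(cand)) {
    i0 <- max(1L, cand[q] - half); i1 <- min(n, cand[q] + half)
    im <- i0 - 1L + which.max(sm[i0:i1])
    delta <- 0
    if (im > 1L && im < n) {
      y0 <- sm[im - 1L]; y1 <- sm[im]; y2 <- sm[im + 1L]
      den <- y0 - 2 * y1 + y2
      if (den < 0) delta <- max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
    }
    ref_idx[q] <- im + delta
    ref_amp[q] <- sm[im]
  }
  ord <- order(ref_idx)
  ref_idx <- ref_idx[ord]; ref_amp <- ref_amp[ord]
  # refractory: within `refractory_s`, keep the larger peak
  min_gap <- refractory_s * fs
  keep_idx <- numeric(0); keep_amp <- numeric(0)
  for (q in seq_along(ref_idx)) {
    if (length(keep_idx) &&
        ref_idx[q] - keep_idx[length(keep_idx)] < min_gap) {
      if (ref_amp[q] > keep_amp[length(keep_amp)]) {
        keep_idx[length(keep_idx)] <- ref_idx[q]
        keep_amp[length(keep_amp)] <- ref_amp[q]
      }
    } else {
      keep_idx <- c(keep_idx, ref_idx[q])
      keep_amp <- c(keep_amp, ref_amp[q])
    }
  }
  structure(list(peak_indices = as.integer(round(keep_idx)),
                 peak_times = (keep_idx - 1) * signal$T,
                 n = diff(keep_idx), T = signal$T, warning_flag = FALSE),
            class = "peak_train")
}

#' Instantaneous heart-rate curve from a peak train
#'
#' One value per adjacent-peak interval: with inter-peak distance `n`
#' samples and sampling interval `T`, the heart rate is `60 / (n * T)`
#' beats per minute, timestamped at the interval's end peak. Values outside
#' (20, 300) bpm are discarded as detection artifacts.
#'
#' @param train A `peak_train` with at least two peaks.
#' @return A `heart_rate_curve`: list with `times` (s) and `fhr_bpm`.
#' @export
compute_heart_rate_curve <- function(train) {
  if (length(train$peak_times) < 2L)
    stop("need at least two peaks to compute a heart-rate curve")
  fhr <- 60 / (train$n * train$T)
  times <- train$peak_times[-1]
  ok <- fhr > 20 & fhr < 300
  structure(list(times = times[ok], fhr_bpm = fhr[ok]),
            class = "heart_rate_curve")
}

# resample two curves onto a shared uniform 1 s grid over their overlap
resample_pair <- function(hr_a, hr_b, grid_s = 1) {
  lo <- max(min(hr_a$times), min(hr_b$times))
  hi <- min(max(hr_a$times), max(hr_b$times))
  if (hi - lo < 60)
    warning("heart-rate curves overlap for only ", round(hi - lo, 1),
            " s (less than 60 s)")
  grid <- seq(ceiling(lo / grid_s) * grid_s, floor(hi / grid_s) * grid_s,
              by = grid_s)
  if (length(grid) < 3L) stop("heart-rate curves barely overlap")
  list(a = approx(hr_a$times, hr_a$fhr_bpm, grid)$y,
       b = approx(hr_b$times, hr_b$fhr_bpm, grid)$y,
       grid = grid)
}

#' Pearson correlation of two heart-rate curves
#'
#' Both curves are linearly resampled onto a shared uniform 1 s grid over
#' their overlap before correlating.
#'
#' @param hr_a,hr_b `heart_rate_curve`s with overlapping spans.
#' @return Pearson correlation coefficient.
#' @export
correlate_heart_rate <- function(hr_a, hr_b) {
  rs <- resample_pair(hr_a, hr_b)
  if (sd(rs$a) == 0 || sd(rs$b) == 0)
    stop("correlation undefined: a heart-rate curve has zero variance")
  cor(rs$a, rs$b)
}

#' Extremum deviation between two heart-rate curves
#'
#' Absolute differences of the curve maxima and minima over the shared
#' overlap (after the same 1 s resampling as [correlate_heart_rate()]).
#'
#' @param hr_a,hr_b `heart_rate_curve`s with overlapping spans.
#' @return Named numeric vector `c(max_dev_bpm, min_dev_bpm)`.
#' @export
extremum_deviation <- function(hr_a, hr_b) {
  rs <- resample_pair(hr_a, hr_b)
  c(max_dev_bpm = abs(max(rs$a) - max(rs$b)),
    min_dev_bpm = abs(min(rs$a) - min(rs$b)))
}

#' Estimate the signal-to-noise ratio by beat-ensemble averaging
#'
#' Beats are windowed around each detected peak (from 35% of the median
#' inter-peak distance before the peak to 45% after it, so neighbouring
#' beats stay outside the window even under rhythm variability), linearly
#' detrended per window to remove residual baseline drift, and averaged
#' into a template. Signal power is the template power. Noise power is the
#' mean residual power after projecting out, per beat, the component along
#' the template derivative (which absorbs sub-sample alignment error, so
#' timing jitter does not masquerade as noise), with a degrees-of-freedom
#' bias correction.
#'
#' @param signal The [ecg_signal()] the peaks were detected on.
#' @param train A `peak_train` with at least 10 usable beats.
#' @return Estimated SNR in dB.
#' @export
estimate_snr <- function(signal, train) {
  fs <- 1 / signal$T
  idx <- round(train$peak_times * fs) + 1L
  if (length(idx) < 10L) stop("SNR estimation needs at least 10 beats")
  rr <- median(diff(idx))
  before <- round(0.35 * rr); after <- round(0.45 * rr)
  L <- before + after + 1L
  n <- length(signal$samples)
  idx <- idx[idx - before >= 1L & idx + after <= n]
  if (length(idx) < 10L) stop("SNR estimation needs at least 10 full beats")
  tt <- seq_len(L) - (L + 1) / 2
  detrend <- function(y) {
    fit <- stats::lm.fit(cbind(1, tt), y)
    y - fit$fitted.values
  }
  M <- vapply(idx, function(i)
    detrend(signal$samples[(i - before):(i + after)]), numeric(L))
  template <- rowMeans(M)
  ps <- mean(template^2)
  nb <- ncol(M)
  resid <- M - template
  dtpl <- c(0, diff(template))
  dd <- sum(dtpl^2)
  if (dd > 0) {
    coef <- colSums(resid * dtpl) / dd
    resid <- resid - outer(dtpl, coef)
  }
  # template subtraction, the two detrend parameters and the alignment
  # projection each consume degrees of freedom
  pn <- mean(resid^2) * nb / (nb - 1) * L / (L - 3)
  10 * log10(ps / pn)
}

#' Fraction of unrecognizable signal
#'
#' Splits the recording into non-overlapping windows and flags a window as
#' unrecognizable when any of three rules fails: the detected beat count
#' must imply 20-300 bpm; the inter-peak intervals must show a coherent
#' rhythm (at least five intervals, with a coefficient of variation below
#' 0.5 -- a handful of stray detections is not rhythm evidence); and the
#' window RMS must lie within a factor 10 of the median window RMS.
#'
#' @param signal A filtered [ecg_signal()] at least three windows long.
#' @param window_s Window length in seconds (default 10).
#' @return Fraction of windows flagged, in `[0, 1]`.
#' @export
unrecognizable_fraction <- function(signal, window_s = 10) {
  fs <- 1 / signal$T
  dur <- signal_duration(signal)
  if (dur < 3 * window_s)
    stop("need at least three windows (", 3 * window_s, " s) of signal")
  nwin <- floor(dur / window_s)
  wlen <- round(window_s * fs)
  rms <- numeric(nwin)
  windows <- vector("list", nwin)
  for (k in seq_len(nwin)) {
    seg <- signal$samples[((k - 1L) * wlen + 1L):(k * wlen)]
    windows[[k]] <- seg
    rms[k] <- sqrt(mean((seg - mean(seg))^2))
  }
  med_rms <- median(rms)
  bad <- logical(nwin)
  for (k in seq_len(nwin)) {
    if (med_rms > 0 && (rms[k] > 10 * med_rms || rms[k] < med_rms / 10)) {
      bad[k] <- TRUE
      next
    }
    seg <- ecg_signal(windows[[k]] + 0, T = signal$T,
                      channel = signal$channel, provenance = "noisy")
    train <- suppressWarnings(detect_beats(seg))
    bpm <- length(train$peak_times) / window_s * 60
    if (bpm < 20 || bpm > 300) {
      bad[k] <- TRUE
      next
    }
    gaps <- diff(train$peak_times)
    if (length(gaps) < 5L || sd(gaps) / mean(gaps) >= 0.5) bad[k] <- TRUE
  }
  mean(bad)
}
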