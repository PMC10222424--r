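#' Uniformly sampled ECG trace
#'
#' @param samples Numeric vector of sample values (finite, length >= 2).
#' @param T Sampling interval in seconds.
#' @param channel Channel label.
#' @param provenance One of `"clean"`, `"noisy"`, `"simulated"`.
#' @return An `ecg_signal`.
#' @export
ecg_signal <- function(samples, T, channel = "ecg",
                       provenance = c("clean", "noisy", "simulated")) {
  provenance <- match.arg(provenance)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("an ECG signal needs at least two samples")
  if (!all(is.finite(samples))) stop("ECG samples must be finite")
  if (!is.finite(T) || T <= 0) stop("sampling interval must be positive")
  structure(list(samples = samples, T = T, channel = channel,
                 provenance = provenance),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal '%s' (%s): %d samples @ %.6g Hz, %.6g s>\n",
              x$channel, x$provenance, length(x$samples), 1 / x$T,
              signal_duration(x)))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param signal An `ecg_signal`.
#' @return Numeric scalar.
#' @export
signal_duration <- function(signal) length(signal$samples) * signal$T

#' Sample times of a signal
#' @param signal An `ecg_signal`.
#' @return Numeric vector, starting at 0.
#' @export
signal_times <- function(signal) (seq_along(signal$samples) - 1) * signal$T

#' Write a signal as CSV
#'
#' The interchange dialect is a UTF-8 CSV with header `time_s,value`,
#' `'.'` decimal separator and 17 significant digits, so that a write-read
#' round trip reproduces the samples exactly.
#'
#' @param signal An `ecg_signal`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(paste(sprintf("%.17g", signal_times(signal)),
                   sprintf("%.17g", signal$samples), sep = ","), con)
  invisible(path)
}

#' Read a signal from CSV
#'
#' Expects the dialect written by [write_signal()]. Timestamps must be
#' uniform to within 1e-6 s.
#'
#' @param path Input file path.
#' @param channel Channel label for the returned signal.
#' @param provenance Provenance label for the returned signal.
#' @return An [ecg_signal()].
#' @export
read_signal <- function(path, channel = basename(path),
                        provenance = "noisy") {
  header <- readLines(path, n = 1L)
  if (!identical(header, "time_s,value"))
    stop("malformed signal file ", path,
         ": expected header 'time_s,value', got '", header, "'")
  d <- read.csv(path, colClasses = "numeric")
  if (nrow(d) < 2L) stop("signal file ", path, " has fewer than two samples")
  dt <- diff(d$time_s)
  if (any(abs(dt - dt[1]) > 1e-6))
    stop("non-uniform timestamps in ", path,
         " (tolerance 1e-6 s); was the file reordered?")
  ecg_signal(d$value, T = mean(dt), channel = channel,
             provenance = provenance)
}
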