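#' Zero-phase Butterworth band-pass
#'
#' Second-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the net phase shift is zero and the effective
#' magnitude response is the square of the single-pass response. Phase
#' integrity matters here because the band-passed series feed the analytic-
#' signal phase extraction.
#'
#' @param x numeric waveform
#' @param fs sampling rate, Hz
#' @param band `c(low, high)` cutoff frequencies in Hz, inside `(0, fs/2)`
#' @param order filter order per band edge (default 2)
#' @return filtered waveform, same length as `x`
#' @export
bandpass <- function(x, fs, band, order = 2) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  if (length(x) <= 3 * (2 * order + 1))
    stop("signal too short for the band-pass filter padding")
  b <- signal::butter(order, band * 2 / fs, type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Band-pass a respiration waveform to the 0.05--0.6 Hz band
#'
#' @param resp respiration waveform
#' @param fs sampling rate, Hz (`>= 2`)
#' @return filtered waveform
#' @export
filter_respiration <- function(resp, fs) {
  if (fs < 2) stop("respiration sampling rate must be >= 2 Hz")
  bandpass(resp, fs, c(0.05, 0.6))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x numeric waveform (zero-mean narrowband input expected)
#' @return complex vector `x + i * H(x)`
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a narrowband signal
#'
#' The angle of the analytic signal, wrapped to `(-pi, pi]`. Amplitude
#' scaling leaves the phase unchanged.
#'
#' @param x numeric waveform
#' @return phase in radians, same length as `x`
#' @export
instantaneous_phase <- function(x) {
  Arg(analytic_signal(x))
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param psi angles in radians
#' @return wrapped angles
#' @export
wrap_phase <- function(psi) {
  w <- (psi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
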