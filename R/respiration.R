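#' Complex Morlet continuous wavelet power
#'
#' CWT of a real signal with the complex Morlet wavelet
#' \eqn{\psi(t) = (\pi f_b)^{-1/2} e^{2\pi i f_c t} e^{-t^2/f_b}}
#' (bandwidth `fb = 1.5`, center frequency `fc = 1.0` in normalized wavelet
#' units), computed in the frequency domain: at scale `s = fc / f` the
#' wavelet's transfer function is `sqrt(s) * exp(-pi^2 fb (s f' - fc)^2)`.
#' Returns squared-modulus coefficients per analysis frequency.
#'
#' @param x real signal
#' @param fs sampling rate, Hz
#' @param freqs analysis frequencies, Hz (ascending)
#' @param fb,fc Morlet bandwidth and center-frequency parameters
#' @return `length(freqs) x length(x)` matrix of wavelet power
#' @export
morlet_cwt_power <- function(x, fs, freqs, fb = 1.5, fc = 1.0) {
  n <- length(x)
  X <- stats::fft(x)
  fgrid <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  P <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- fc / freqs[i]
    Psi <- sqrt(s) * exp(-pi^2 * fb * (s * fgrid - fc)^2)
    w <- stats::fft(X * Psi, inverse = TRUE) / n
    P[i, ] <- Mod(w)^2
  }
  P
}

# log-spaced analysis frequencies spanning the respiration band
resp_freq_grid <- function(n_scales = 128, band = c(0.05, 0.6)) {
  exp(seq(log(band[1]), log(band[2]), length.out = n_scales))
}

#' Dominant respiratory frequency of one 20 s window
#'
#' Wavelet power spectral density of the (band-passed) respiration signal,
#' averaged over the window; the estimate is the analysis frequency with
#' maximal average power, ties broken toward the lowest frequency. An
#' all-zero window yields `NA` (flagged missing, not an error).
#'
#' @param resp_window ~20 s of filtered respiration
#' @param fs sampling rate, Hz
#' @param n_scales number of log-spaced analysis frequencies across
#'   0.05--0.6 Hz (default 128)
#' @return dominant frequency `f_R` in Hz, or `NA_real_`
#' @export
estimate_resp_frequency <- function(resp_window, fs, n_scales = 128) {
  if (all(resp_window == 0) || length(resp_window) < 4) return(NA_real_)
  freqs <- resp_freq_grid(n_scales)
  P <- morlet_cwt_power(resp_window, fs, freqs)
  avg <- rowMeans(P)
  freqs[which.max(avg)]   # which.max returns the first (lowest-f) maximum
}

# Respiratory frequency for every 10 s parameter window (5 s slide) of a
# full record. The CWT is computed once over the whole signal; each
# window's PSD averages the power over a 20 s span centered on the 10 s
# window (5 s margin each side), truncated at the record edges.
# Missing estimates (all-zero spans) carry the last valid value forward;
# a miss on the first window falls back to the band center 0.325 Hz.
resp_frequency_series <- function(resp_filtered, fs, n_windows,
                                  n_scales = 128) {
  freqs <- resp_freq_grid(n_scales)
  P <- morlet_cwt_power(resp_filtered, fs, freqs)
  n <- length(resp_filtered)
  f_R <- numeric(n_windows)
  last <- NA_real_
  for (k in seq_len(n_windows)) {
    t0 <- (k - 1) * 5 - 5
    t1 <- t0 + 20
    i0 <- max(1L, as.integer(floor(t0 * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling(t1 * fs)))
    est <- NA_real_
    if (i1 >= i0 && any(resp_filtered[i0:i1] != 0)) {
      avg <- rowMeans(P[, i0:i1, drop = FALSE])
      est <- freqs[which.max(avg)]
    }
    if (is.na(est)) est <- if (is.na(last)) 0.325 else last
    f_R[k] <- est
    last <- est
  }
  f_R
}
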