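#' Detect body movements from the anterior-tibialis EMG
#'
#' The EMG is band-passed 1--30 Hz (zero-phase Butterworth), normalized by a
#' robust baseline SD (median absolute deviation x 1.4826 over the whole
#' night, excluding LV samples), and scanned in 10 s windows sliding by 5 s:
#' a window scores 1 when any normalized sample exceeds 3 baseline SDs in
#' absolute value, else 0.
#'
#' @param emg EMG waveform
#' @param fs sampling rate, Hz (`> 60`; the 30 Hz band edge must sit below
#'   Nyquist)
#' @param n_windows number of 10 s windows to score (windows are
#'   `[5k, 5k + 10)` seconds, `k = 0, ..., n_windows - 1`, clipped at the
#'   record end). Default covers the record.
#' @param lv_mask optional per-sample logical; `TRUE` samples are excluded
#'   from the baseline estimate and never trigger a detection
#' @param threshold detection threshold in baseline SDs (default 3)
#' @return integer 0/1 vector of length `n_windows`
#' @export
detect_body_movements <- function(emg, fs, n_windows = NULL, lv_mask = NULL,
                                  threshold = 3) {
  if (fs <= 60) stop("EMG sampling rate must exceed 60 Hz")
  filt <- bandpass(emg, fs, c(1, 30))
  base <- if (is.null(lv_mask)) filt else filt[!lv_mask]
  base_sd <- stats::mad(base)
  if (base_sd <= 0) base_sd <- stats::sd(base)
  if (!is.finite(base_sd) || base_sd <= 0) base_sd <- 1
  z <- abs(filt) / base_sd
  if (!is.null(lv_mask)) z[lv_mask] <- 0
  n <- length(emg)
  if (is.null(n_windows)) n_windows <- max(1L, as.integer(floor((n / fs - 10) / 5)) + 1L)
  hit <- z > threshold
  out <- integer(n_windows)
  for (k in seq_len(n_windows)) {
    i0 <- as.integer(floor((k - 1) * 5 * fs)) + 1L
    i1 <- min(n, as.integer(ceiling(((k - 1) * 5 + 10) * fs)))
    if (i0 <= i1 && any(hit[i0:i1])) out[k] <- 1L
  }
  out
}

#' Count distinct movement events
#'
#' Connected suprathreshold excursions of the filtered, normalized EMG,
#' merged when separated by less than `merge_gap_s` seconds, are counted as
#' single events. Complements [detect_body_movements()] (whose per-window
#' binaries feed the BMF feature) when an event count is needed, e.g. to
#' compare against a generator's ground-truth burst count.
#'
#' @inheritParams detect_body_movements
#' @param merge_gap_s events closer than this are merged (default 0.5 s)
#' @return integer event count
#' @export
count_movement_events <- function(emg, fs, lv_mask = NULL, threshold = 3,
                                  merge_gap_s = 0.5) {
  if (fs <= 60) stop("EMG sampling rate must exceed 60 Hz")
  filt <- bandpass(emg, fs, c(1, 30))
  base <- if (is.null(lv_mask)) filt else filt[!lv_mask]
  base_sd <- stats::mad(base)
  if (!is.finite(base_sd) || base_sd <= 0) base_sd <- 1
  z <- abs(filt) / base_sd
  if (!is.null(lv_mask)) z[lv_mask] <- 0
  hit <- which(z > threshold)
  if (length(hit) == 0) return(0L)
  gaps <- diff(hit) > merge_gap_s * fs
  as.integer(1L + sum(gaps))
}
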