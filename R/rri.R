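#' Automated RRI outlier screen
#'
#' Deterministic surrogate for visual tachogram inspection. Works on
#' tachogram points `(t, rri)`, where `t` is the time of the beat ending
#' each interval: a point is dropped when its RRI falls outside the
#' physiological range 300--2000 ms, or when it differs by more than 30%
#' from the median of the five preceding accepted RRIs. Dropping the point
#' (rather than the beat) mirrors deleting an artifactual interval from the
#' tachogram while keeping later beats as anchors, so an isolated artifact
#' or a signal gap does not cascade.
#'
#' @param beat_times strictly increasing beat times, seconds (length n)
#' @param rri R-R intervals in ms. Either length `n - 1`
#'   (`rri[i]` = interval ending at `beat_times[i + 1]`) or a tachogram
#'   already paired with `beat_times` (equal lengths).
#' @return `list(time_s, rri_ms)` of accepted tachogram points, strictly
#'   increasing in time
#' @export
clean_rri <- function(beat_times, rri) {
  if (any(diff(beat_times) <= 0)) stop("beat_times must be strictly increasing")
  if (length(rri) == length(beat_times) - 1) {
    t <- beat_times[-1]
  } else if (length(rri) == length(beat_times)) {
    t <- beat_times
  } else stop("rri length must equal length(beat_times) or length(beat_times) - 1")
  keep <- logical(length(rri))
  accepted <- numeric(0)
  for (i in seq_along(rri)) {
    r <- rri[i]
    ok <- r >= 300 && r <= 2000
    if (ok && length(accepted) >= 1) {
      m <- stats::median(utils::tail(accepted, 5))
      ok <- abs(r - m) <= 0.3 * m
    }
    if (ok) {
      keep[i] <- TRUE
      accepted <- c(accepted, r)
    }
  }
  if (sum(keep) < 2) stop("insufficient beats after RRI cleaning")
  list(time_s = t[keep], rri_ms = rri[keep])
}

#' Resample a cleaned tachogram to a uniform 10 Hz grid
#'
#' Cubic spline through the `(time, rri)` points, evaluated on an
#' equidistant 0.1 s grid. Heart rate is `60000 / rri` (beats/min).
#'
#' @param time_s strictly increasing tachogram times, seconds (`>= 4` points)
#' @param rri_ms R-R intervals, ms
#' @param grid optional explicit evaluation grid (seconds). Default spans
#'   `[first, last]` point at 0.1 s spacing. Points outside the data range
#'   are spline-extrapolated.
#' @return `list(t, rri, hr)` on the grid
#' @export
resample_rri <- function(time_s, rri_ms, grid = NULL) {
  if (any(diff(time_s) <= 0)) stop("tachogram times must be strictly increasing")
  if (length(time_s) < 4) stop("need at least 4 points for cubic spline resampling")
  if (is.null(grid)) {
    grid <- seq(time_s[1], time_s[length(time_s)], by = 0.1)
  }
  sf <- stats::splinefun(time_s, rri_ms, method = "fmm")
  rri <- sf(grid)
  # the tachogram is screened to the 300-2000 ms physiological range; hold
  # the interpolant to the same range so spline excursions across signal
  # gaps (e.g. out-of-bed spans with no beats) cannot produce absurd rates
  rri <- clip(rri, 300, 2000)
  list(t = grid, rri = rri, hr = 60000 / rri)
}

#' Extract respiratory sinus arrhythmia from the resampled RRI series
#'
#' Zero-phase band-pass of the 10 Hz RRI series over +/- 50% of the dominant
#' respiratory frequency, i.e. `[0.5 f_R, 1.5 f_R]`.
#'
#' @param rri resampled RRI values (ms) on a uniform grid
#' @param f_R dominant respiratory frequency, Hz (`> 0`; `1.5 f_R` must stay
#'   below the 5 Hz Nyquist limit of the 10 Hz grid)
#' @param fs grid sampling rate, Hz (default 10)
#' @return RSA waveform (ms), same length
#' @export
extract_rsa <- function(rri, f_R, fs = 10) {
  if (!is.finite(f_R) || f_R <= 0) stop("degenerate RSA band: f_R must be > 0")
  if (1.5 * f_R >= fs / 2) stop("degenerate RSA band: 1.5 * f_R reaches Nyquist")
  bandpass(rri, fs, c(0.5, 1.5) * f_R)
}
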