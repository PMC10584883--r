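#' Epoch-aligned feature extraction
#'
#' Turns one night's raw channels into the four per-epoch parameters that
#' feed the sequence classifier. All parameters are first computed on 10 s
#' windows sliding by 5 s (window `k` spans `[5k, 5k + 10)` seconds,
#' 0-based, the last window truncated at the record end), then HR, RR and
#' lambda are smoothed with a 6-point (30 s) median filter and averaged over
#' the six windows inside each 30 s epoch; BMF is the count of
#' movement-positive windows in the epoch divided by 30 s. Per window:
#'
#' * HR: mean of `60000 / RRI` on the spline-resampled 10 Hz tachogram
#'   (after the automated outlier screen of [clean_rri()]);
#' * RR: `60 f_R`, with `f_R` from the complex-Morlet wavelet PSD of the
#'   0.05--0.6 Hz band-passed respiration over a 20 s span centered on the
#'   window;
#' * lambda: phase coherence of the RSA-vs-respiration phase difference over
#'   the trailing 100 samples (10 s at 10 Hz) ending at the window's end,
#'   where RSA is the RRI series band-passed to +/- 50% of the night-median
#'   dominant respiratory frequency and both phases come from the analytic
#'   signal;
#' * movement: any filtered, normalized EMG sample beyond 3 baseline SDs.
#'
#' Epochs labelled `LV` ("out of bed") yield all-zero feature rows.
#'
#' @param bundle a `signal_bundle` (see [simulate_signals()]) or a list with
#'   the same fields
#' @param hyp the night's [hypnogram()]; its length fixes the epoch count
#' @return a data.frame (`epoch` 0-based, `hr`, `rr`, `lam`, `bmf`, `stage`)
#'   with one row per hypnogram epoch
#' @export
compute_feature_epochs <- function(bundle, hyp) {
  n_epochs <- length(hyp)
  stopifnot(n_epochs >= 1)
  dur <- n_epochs * 30
  K <- 6L * n_epochs                     # 10 s windows, 5 s slide
  lab <- as.character(hyp)
  fs_r <- bundle$resp_sampling_hz %||% 10
  fs_e <- bundle$emg_sampling_hz %||% 200
  if (length(bundle$respiration) < dur * fs_r - 0.5 ||
      length(bundle$emg) < dur * fs_e - 0.5)
    stop(sprintf("channel durations do not cover the hypnogram span (%d epochs = %g s)",
                 n_epochs, dur))

  # --- tachogram -> 10 Hz HR ---
  tach <- clean_rri(bundle$beat_times, bundle$rri)
  grid <- seq(0, dur - 0.1, by = 0.1)
  res <- resample_rri(tach$time_s, tach$rri_ms, grid = grid)
  n_grid <- length(grid)

  # --- respiration: band-pass, dominant frequency, phase ---
  resp_f <- filter_respiration(bundle$respiration, fs_r)
  f_R <- resp_frequency_series(resp_f, fs_r, K)
  resp10 <- if (abs(fs_r - 10) < 1e-9) resp_f[seq_len(n_grid)] else
    stats::approx((seq_along(resp_f) - 1) / fs_r, resp_f, xout = grid, rule = 2)$y

  # --- RSA and phase coherence on the common 10 Hz grid ---
  f_med <- stats::median(f_R, na.rm = TRUE)
  rsa <- extract_rsa(res$rri, f_med, fs = 10)
  psi <- wrap_phase(instantaneous_phase(rsa) - instantaneous_phase(resp10))
  lam_series <- phase_coherence(psi, n_window = 100)

  # --- EMG movement windows ---
  mov <- detect_body_movements(bundle$emg, fs_e, n_windows = K,
                               lv_mask = bundle$lv_mask_emg)

  # --- per-window values ---
  w_hr <- numeric(K); w_lam <- numeric(K)
  for (k in seq_len(K)) {
    i0 <- (k - 1L) * 50L + 1L
    i1 <- min(n_grid, i0 + 99L)
    w_hr[k] <- mean(res$hr[i0:i1])
    w_lam[k] <- lam_series[i1]
  }
  w_rr <- 60 * f_R

  # --- 30 s (6-point) median filter, shrinking at the edges ---
  medfilt6 <- function(v) {
    out <- numeric(length(v))
    for (j in seq_along(v)) {
      i0 <- max(1L, j - 2L); i1 <- min(length(v), j + 3L)
      out[j] <- stats::median(v[i0:i1])
    }
    out
  }
  w_hr <- medfilt6(w_hr); w_rr <- medfilt6(w_rr); w_lam <- medfilt6(w_lam)

  # --- epoch aggregation ---
  ep <- rep(seq_len(n_epochs), each = 6L)
  hr <- as.numeric(tapply(w_hr, ep, mean))
  rr <- as.numeric(tapply(w_rr, ep, mean))
  lam <- as.numeric(tapply(w_lam, ep, mean))
  bmf <- as.numeric(tapply(mov, ep, sum)) / 30

  out <- data.frame(epoch = seq_len(n_epochs) - 1L,
                    hr = hr, rr = rr, lam = lam, bmf = bmf,
                    stage = lab, stringsAsFactors = FALSE)
  zero <- lab == "LV"
  out$hr[zero] <- 0; out$rr[zero] <- 0; out$lam[zero] <- 0; out$bmf[zero] <- 0
  if (nrow(out) != n_epochs)
    stop(sprintf("feature/label misalignment: expected %d rows, got %d",
                 n_epochs, nrow(out)))
  out
}

#' Pad a night with LV epochs at both ends
#'
#' Prepends and appends four all-zero feature rows labelled `LV`, giving the
#' classifier extra examples of the minority "out of bed" state at every
#' sequence boundary. Length grows by exactly 8; applying twice grows it by
#' 16 (no idempotence).
#'
#' @param features feature data.frame as from [compute_feature_epochs()]
#' @param hyp matching [hypnogram()]
#' @param n_pad epochs added per end (default 4)
#' @return `list(features, hypnogram)`
#' @export
pad_lv <- function(features, hyp, n_pad = 4L) {
  stopifnot(nrow(features) == length(hyp))
  zero_row <- data.frame(epoch = rep(0L, n_pad), hr = 0, rr = 0, lam = 0,
                         bmf = 0, stringsAsFactors = FALSE)
  if ("stage" %in% names(features) || nrow(features) == 0)
    zero_row$stage <- "LV"
  if (nrow(features) == 0) features <- zero_row[0, , drop = FALSE]
  out <- rbind(zero_row[names(features)], features, zero_row[names(features)])
  out$epoch <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  list(features = out,
       hypnogram = hypnogram(c(rep("LV", n_pad), as.character(hyp),
                               rep("LV", n_pad))))
}

#' Read / write an epoch feature table as CSV
#'
#' Columns `epoch, hr_bpm, rr_brpm, lambda, bmf_per_s` plus `stage` when
#' labels are present.
#'
#' @param features feature data.frame
#' @param path file path
#' @export
write_features <- function(features, path) {
  df <- data.frame(epoch = features$epoch, hr_bpm = features$hr,
                   rr_brpm = features$rr, lambda = features$lam,
                   bmf_per_s = features$bmf)
  if ("stage" %in% names(features)) df$stage <- features$stage
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(epoch = df$epoch, hr = df$hr_bpm, rr = df$rr_brpm,
                    lam = df$lambda, bmf = df$bmf_per_s,
                    stringsAsFactors = FALSE)
  if ("stage" %in% names(df)) out$stage <- df$stage
  out
}
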