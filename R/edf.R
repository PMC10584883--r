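# Minimal European Data Format (EDF) support: continuous 16-bit records,
# enough to exchange respiration/EMG channels with PSG software. Values
# round-trip within the 16-bit quantization of each channel's physical
# range.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write waveform channels to an EDF file
#'
#' @param signals named list; each element `list(data, fs)` with `data` a
#'   numeric waveform and `fs` its sampling rate in Hz (integer samples per
#'   1 s data record)
#' @param path output path
#' @param patient,recording free-text header fields
#' @return `path`, invisibly
#' @export
write_edf <- function(signals, path, patient = "X", recording = "synthetic") {
  ns <- length(signals)
  stopifnot(ns >= 1, !is.null(names(signals)))
  fs <- vapply(signals, function(s) s$fs, numeric(1))
  stopifnot(all(abs(fs - round(fs)) < 1e-9))
  n_rec <- min(vapply(signals, function(s) floor(length(s$data) / s$fs), numeric(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256 + 256 * ns
  wf <- function(x, w) writeChar(pad_field(x, w), con, nchars = w, eos = NULL)
  wf("0", 8); wf(patient, 80); wf(recording, 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(hdr_bytes, 8); wf("", 44); wf(n_rec, 8); wf(1, 8); wf(ns, 4)
  pmin <- numeric(ns); pmax <- numeric(ns)
  for (i in seq_len(ns)) {
    r <- range(signals[[i]]$data)
    if (r[1] == r[2]) r <- r + c(-1, 1)
    pmin[i] <- r[1]; pmax[i] <- r[2]
  }
  for (nm in names(signals)) wf(nm, 16)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf("au", 8)
  for (i in seq_len(ns)) wf(signif(pmin[i], 7), 8)
  for (i in seq_len(ns)) wf(signif(pmax[i], 7), 8)
  for (i in seq_len(ns)) wf(-32768, 8)
  for (i in seq_len(ns)) wf(32767, 8)
  for (i in seq_len(ns)) wf("", 80)
  for (i in seq_len(ns)) wf(round(fs[i]), 8)
  for (i in seq_len(ns)) wf("", 32)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      x <- signals[[i]]$data[((r - 1) * fs[i] + 1):(r * fs[i])]
      dig <- round((x - pmin[i]) / (pmax[i] - pmin[i]) * 65535 - 32768)
      writeBin(as.integer(clip(dig, -32768, 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports continuous EDF with 16-bit samples. Returns every requested
#' channel rescaled to physical units.
#'
#' @param path EDF file
#' @param channels optional character vector of channel labels to extract
#'   (default: all)
#' @return list with `header` (named fields) and `signals` (named list of
#'   `list(data, fs)`)
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rf <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    if (length(raw) == 0 || nchar(raw, type = "bytes") < w)
      stop("truncated EDF header in ", path)
    trimws(raw)
  }
  version <- rf(8); patient <- rf(80); recording <- rf(80)
  startdate <- rf(8); starttime <- rf(8)
  hdr_bytes <- as.integer(rf(8)); rf(44)
  n_rec <- as.integer(rf(8)); rec_dur <- as.numeric(rf(8))
  ns <- as.integer(rf(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)
  rfv <- function(w) vapply(seq_len(ns), function(i) rf(w), character(1))
  labels <- rfv(16); rfv(80); rfv(8)
  pmin <- as.numeric(rfv(8)); pmax <- as.numeric(rfv(8))
  dmin <- as.numeric(rfv(8)); dmax <- as.numeric(rfv(8))
  rfv(80)
  spr <- as.integer(rfv(8)); rfv(32)
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, labels)
    if (length(missing_ch) > 0)
      stop(sprintf("channel '%s' not found; available channels: %s",
                   missing_ch[1], paste(labels, collapse = ", ")))
  }
  want <- if (is.null(channels)) labels else channels
  idx <- match(want, labels)
  out <- stats::setNames(lapply(want, function(w)
    list(data = numeric(0), fs = NA_real_)), want)
  store <- lapply(seq_len(ns), function(i) vector("list", n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, integer(), n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i])
        stop(sprintf("truncated EDF data: record %d of %d in %s", r, n_rec, path))
      if (i %in% idx) store[[i]][[r]] <- v
    }
  }
  for (j in seq_along(want)) {
    i <- idx[j]
    dig <- unlist(store[[i]])
    phys <- (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
    out[[j]] <- list(data = phys, fs = spr[i] / rec_dur)
  }
  list(header = list(version = version, patient = patient,
                     recording = recording, startdate = startdate,
                     starttime = starttime, n_records = n_rec,
                     record_duration = rec_dur, labels = labels),
       signals = out)
}

#' Assemble a signal bundle from an EDF file plus a beat list
#'
#' Extracts the named respiration and EMG channels at their native rates;
#' beats come from a sidecar CSV (`time_s[, rri_ms]`), since R-peak
#' detection from raw ECG is outside this package's scope.
#'
#' @param path EDF file
#' @param channel_map `list(respiration = "<label>", emg = "<label>")`
#' @param beats_csv path to the beat-list CSV
#' @return a `signal_bundle` list (no LV masks; supply separately if known)
#' @export
read_psg_edf <- function(path, channel_map, beats_csv) {
  ed <- read_edf(path, channels = c(channel_map$respiration, channel_map$emg))
  beats <- utils::read.csv(beats_csv)
  bt <- beats$time_s
  rri <- if ("rri_ms" %in% names(beats) && !all(is.na(beats$rri_ms)))
    beats$rri_ms[-1] else diff(bt) * 1000
  structure(list(beat_times = bt, rri = rri,
                 respiration = ed$signals[[channel_map$respiration]]$data,
                 emg = ed$signals[[channel_map$emg]]$data,
                 resp_sampling_hz = ed$signals[[channel_map$respiration]]$fs,
                 emg_sampling_hz = ed$signals[[channel_map$emg]]$fs,
                 lv_mask_resp = NULL, lv_mask_emg = NULL,
                 ground_truth = NULL), class = "signal_bundle")
}
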