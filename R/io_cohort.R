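#' Write / read a synthetic cohort as plain-text files
#'
#' One directory per subject containing `beats.csv` (`time_s, rri_ms`; the
#' first beat has an empty interval), `resp.csv` and `emg.csv`
#' (sample-indexed `value` columns), `hypnogram.txt` (one label per line)
#' and `meta.json` (sampling rates, covariates); plus a cohort-level
#' `manifest.json` listing subjects and the generating seed. The pair of
#' functions round-trips losslessly up to numeric text formatting.
#'
#' @param cohort output of [simulate_cohort()]
#' @param dir target directory (created if needed)
#' @param seed optional generating seed recorded in the manifest
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort) {
    sd_ <- file.path(dir, subj$id)
    dir.create(sd_, showWarnings = FALSE)
    sig <- subj$signals
    utils::write.csv(
      data.frame(time_s = sig$beat_times,
                 rri_ms = c(NA_real_, sig$rri)),
      file.path(sd_, "beats.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(value = sig$respiration),
                     file.path(sd_, "resp.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(value = sig$emg),
                     file.path(sd_, "emg.csv"), row.names = FALSE, quote = FALSE)
    write_hypnogram(subj$hypnogram, file.path(sd_, "hypnogram.txt"))
    jsonlite::write_json(
      list(id = subj$id, ahi = subj$ahi,
           resp_sampling_hz = sig$resp_sampling_hz,
           emg_sampling_hz = sig$emg_sampling_hz),
      file.path(sd_, "meta.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(subjects = vapply(cohort, `[[`, character(1), "id"),
         seed = seed, n_subjects = length(cohort)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort` returns a list of subjects shaped like the output
#'   of [simulate_cohort()] (LV masks reconstructed from the hypnogram).
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  subjects <- lapply(man$subjects, function(id) {
    sd_ <- file.path(dir, id)
    meta <- jsonlite::read_json(file.path(sd_, "meta.json"),
                                simplifyVector = TRUE)
    beats <- utils::read.csv(file.path(sd_, "beats.csv"))
    resp <- utils::read.csv(file.path(sd_, "resp.csv"))$value
    emg <- utils::read.csv(file.path(sd_, "emg.csv"))$value
    hyp <- read_hypnogram(file.path(sd_, "hypnogram.txt"))
    n_ep <- length(hyp)
    lv <- as.character(hyp) == "LV"
    mask_of <- function(n, fs) lv[pmin(floor((seq_len(n) - 1) / fs / 30) + 1, n_ep)]
    sig <- structure(list(
      beat_times = beats$time_s,
      rri = beats$rri_ms[-1],
      respiration = resp, emg = emg,
      resp_sampling_hz = meta$resp_sampling_hz,
      emg_sampling_hz = meta$emg_sampling_hz,
      lv_mask_resp = mask_of(length(resp), meta$resp_sampling_hz),
      lv_mask_emg = mask_of(length(emg), meta$emg_sampling_hz),
      ground_truth = NULL), class = "signal_bundle")
    list(id = id, hypnogram = hyp, signals = sig, ahi = meta$ahi)
  })
  names(subjects) <- man$subjects
  subjects
}
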