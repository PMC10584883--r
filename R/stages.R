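#' Stage alphabets
#'
#' `STAGES5` is the five-class AASM-style alphabet (wake, REM, and the three
#' non-REM depths). `STAGES6` adds `LV`, the "getting out of bed" state used
#' when all channels drop out for more than two epochs; `LV` is merged into
#' `WK` before any agreement metric is computed.
#'
#' @format Character vectors.
#' @export
STAGES5 <- c("WK", "REM", "N1", "N2", "N3")

#' @rdname STAGES5
#' @export
STAGES6 <- c("WK", "REM", "N1", "N2", "N3", "LV")

#' Network class order
#'
#' Fixed ordering of the six output classes (`N1, N2, N3, REM, WK, LV`);
#' probability matrices returned by [predict_stages()] follow it, and
#' argmax ties break toward the lower index.
#'
#' @format Character vector of length 6.
#' @export
CLASS_ORDER <- c("N1", "N2", "N3", "REM", "WK", "LV")

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch (30 s) sequence of sleep-stage labels for one
#' night, drawn from the six-stage alphabet [STAGES6].
#'
#' @param labels character vector of stage labels (case-insensitive)
#' @param epoch_seconds epoch duration; fixed at 30 s
#' @return a character vector of validated labels with class `"hypnogram"`
#' @export
hypnogram <- function(labels, epoch_seconds = 30) {
  labels <- toupper(as.character(labels))
  bad <- which(!labels %in% STAGES6)
  if (length(bad) > 0) {
    stop(sprintf("unknown stage label '%s' at epoch %d", labels[bad[1]], bad[1]))
  }
  structure(labels, class = "hypnogram", epoch_seconds = epoch_seconds)
}

#' Read / write a hypnogram as plain text, one label per line
#'
#' Round-trips losslessly: `read_hypnogram(write_hypnogram(h, f))` equals `h`.
#' Unknown tokens raise an error naming the offending line; an empty file
#' yields an empty hypnogram with a warning.
#'
#' @param path file path
#' @return `read_hypnogram` returns a [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty hypnogram file: ", path)
    return(hypnogram(character(0)))
  }
  up <- toupper(lines)
  bad <- which(!up %in% STAGES6)
  if (length(bad) > 0) {
    stop(sprintf("unknown stage token '%s' at line %d of %s",
                 lines[bad[1]], bad[1], path))
  }
  hypnogram(up)
}

#' @rdname read_hypnogram
#' @param h a [hypnogram()]
#' @export
write_hypnogram <- function(h, path) {
  writeLines(as.character(h), path)
  invisible(path)
}
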