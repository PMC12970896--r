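#' Construct a single-channel EEG recording
#'
#' A recording holds one calibrated single-channel EEG trace together with its
#' sampling rate, an identifier used for provenance (fold assignment and
#' differencing never cross recording boundaries), and an optional state label
#' such as `"interictal"`, `"preictal"`, `"ictal"`, `"seizure"` or
#' `"non-seizure"`.
#'
#' @param samples Numeric vector of amplitude values. Multiplied by
#'   `calibration` so that stored samples are in microvolts.
#' @param fs Sampling frequency in Hz (> 0).
#' @param recording_id Unique identifier string.
#' @param label Optional state label (`NA` if unlabeled).
#' @param calibration Multiplicative microvolt-per-unit factor (> 0) applied to
#'   `samples`. Raw files often store ADC units; the duration-amplitude wave
#'   criteria are expressed in microvolts, so calibrate before feature
#'   extraction.
#' @return An object of class `eeg_recording`: a list with elements `samples`
#'   (microvolts), `fs`, `recording_id`, `label`, `calibration`.
#' @examples
#' rec <- recording(sin(seq(0, 10, by = 0.01)), fs = 100, recording_id = "demo")
#' rec
#' @export
recording <- function(samples, fs, recording_id, label = NA_character_,
                      calibration = 1) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive number")
  if (!is.numeric(calibration) || length(calibration) != 1L || calibration <= 0)
    stop("calibration must be a positive number")
  structure(
    list(samples = samples * calibration,
         fs = as.numeric(fs),
         recording_id = as.character(recording_id),
         label = as.character(label),
         calibration = as.numeric(calibration)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording '%s'> %d samples @ %.5g Hz (%.3f s)%s\n",
              x$recording_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.na(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' @export
length.eeg_recording <- function(x) length(x$samples)

#' Read a plain-text EEG segment (one sample value per line)
#'
#' Reads the ASCII dialect used by the Bonn epilepsy corpus: one numeric
#' amplitude value per line, a fixed sampling rate per corpus (173.61 Hz, 4097
#' samples per 23.6 s segment for Bonn). Raw values are typically ADC units;
#' pass `calibration` to convert to microvolts. A warning is emitted when
#' `calibration = 1` is used, because the spike/sharp-wave criteria downstream
#' assume microvolt units.
#'
#' @param path Path to the text file.
#' @param fs Sampling frequency in Hz (default 173.61).
#' @param calibration Microvolt-per-unit factor (default 1).
#' @param label Optional state label attached to the recording.
#' @param recording_id Identifier; defaults to the file name without extension.
#' @param warn_calibration Emit the calibration warning (default TRUE).
#' @return An [recording()] object.
#' @export
read_bonn_text <- function(path, fs = 173.61, calibration = 1,
                           label = NA_character_, recording_id = NULL,
                           warn_calibration = TRUE) {
  lines <- readLines(path)
  # tolerate trailing blank lines only
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("empty file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric value at line %d of %s: '%s'", bad, path, lines[bad]))
  }
  if (isTRUE(warn_calibration) && calibration == 1)
    warning("calibration = 1: samples are assumed to already be in microvolts; ",
            "microvolt amplitude thresholds apply to these raw values")
  if (is.null(recording_id))
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  recording(vals, fs = fs, recording_id = recording_id, label = label,
            calibration = calibration)
}

#' Write a recording in the plain-text one-sample-per-line dialect
#'
#' Integer-valued samples are written as integers so a read/write/read
#' round-trip of integer ADC data is lossless.
#'
#' @param rec An [recording()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bonn_text <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$samples
  txt <- ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
                sprintf("%.12g", x))
  writeLines(txt, path)
  invisible(path)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Optional preprocessing hook: 4th-order Butterworth band-pass applied
#' forward and backward (zero phase). The 0.5-70 Hz default matches common
#' clinical EEG band limits. Off by default throughout the package; call
#' explicitly when wanted.
#'
#' @param rec An [recording()] object.
#' @param lo,hi Band edges in Hz (0 < lo < hi < fs/2).
#' @param order Filter order (default 4).
#' @return A filtered copy of `rec`.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 70, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && hi > lo && hi < nyq))
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  rec$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  rec
}
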