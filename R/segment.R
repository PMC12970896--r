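#' Segment a recording into overlapping fixed-length windows
#'
#' Splits a recording with a sliding window (default 256 samples with 50%
#' overlap, i.e., a hop of 128 samples). Window starts form the arithmetic
#' sequence 0, hop, 2 hop, ...; a trailing partial window is discarded, so a
#' recording of n samples yields `floor((n - window_len) / hop) + 1` windows
#' (0 when n < window_len). Windows inherit the recording's id and label so
#' downstream fold assignment and temporal differencing never cross recording
#' boundaries.
#'
#' @param rec An [recording()] object.
#' @param window_len Window length in samples (default 256, >= 2).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5). The hop is
#'   `round(window_len * (1 - overlap))` and must be >= 1.
#' @return An object of class `eeg_windows`: list with `samples` (matrix,
#'   one row per window), `meta` (data.frame with `recording_id`,
#'   `window_index` (0-based), `start_sample` (0-based), `label`), and `fs`.
#' @examples
#' rec <- recording(rnorm(1024), fs = 200, recording_id = "r1")
#' w <- segment(rec)
#' nrow(w$samples)  # 7 windows
#' @export
segment <- function(rec, window_len = 256, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  window_len <- as.integer(window_len)
  if (window_len < 2L) stop("window_len must be >= 2")
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)")
  hop <- as.integer(round(window_len * (1 - overlap)))
  if (hop < 1L) stop("hop round(window_len * (1 - overlap)) must be >= 1")
  n <- length(rec$samples)
  n_win <- if (n >= window_len) (n - window_len) %/% hop + 1L else 0L
  if (n_win == 0L) {
    samples <- matrix(numeric(0), nrow = 0L, ncol = window_len)
    meta <- data.frame(recording_id = character(0), window_index = integer(0),
                       start_sample = integer(0), label = character(0),
                       stringsAsFactors = FALSE)
  } else {
    starts <- (seq_len(n_win) - 1L) * hop           # 0-based offsets
    samples <- t(vapply(starts, function(s) rec$samples[(s + 1L):(s + window_len)],
                        numeric(window_len)))
    meta <- data.frame(recording_id = rec$recording_id,
                       window_index = seq_len(n_win) - 1L,
                       start_sample = starts,
                       label = rec$label,
                       stringsAsFactors = FALSE)
  }
  structure(list(samples = samples, meta = meta, fs = rec$fs,
                 window_len = window_len, hop = hop),
            class = "eeg_windows")
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %d windows of %d samples (hop %d) from '%s'\n",
              nrow(x$samples), x$window_len, x$hop,
              paste(unique(x$meta$recording_id), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.eeg_windows <- function(x, ...) x$meta
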