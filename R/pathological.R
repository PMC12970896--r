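#' Duration-amplitude criteria for pathological transients
#'
#' Clinical duration-amplitude definitions of the two transient classes:
#' spike waves last 20-70 ms with amplitude above 50 microvolts; sharp waves
#' last 70-200 ms with amplitude of roughly 100-200 microvolts. The shared
#' 70 ms boundary is assigned to sharp waves (the spike duration interval is
#' right-open), a deterministic tie-break. The sharp amplitude ceiling can be
#' relaxed to `Inf` since the clinical range is approximate.
#'
#' @param spike_duration_ms Spike duration interval `[lo, hi)` in ms.
#' @param spike_amplitude_uv Spike amplitude interval `[lo, hi]` in microvolts.
#' @param sharp_duration_ms Sharp-wave duration interval `[lo, hi]` in ms.
#' @param sharp_amplitude_uv Sharp-wave amplitude interval `[lo, hi]`.
#' @return A list of two criterion records (checked spike-first), each with
#'   `wave_class`, `duration_ms`, `duration_hi_open`, `amplitude_uv`.
#' @export
wave_criteria <- function(spike_duration_ms = c(20, 70),
                          spike_amplitude_uv = c(50, Inf),
                          sharp_duration_ms = c(70, 200),
                          sharp_amplitude_uv = c(100, 200)) {
  chk <- function(b, name) {
    if (length(b) != 2L || !is.numeric(b) || b[1] < 0 || b[2] <= b[1])
      stop(name, " must be an increasing nonnegative pair")
  }
  chk(spike_duration_ms, "spike_duration_ms")
  chk(spike_amplitude_uv, "spike_amplitude_uv")
  chk(sharp_duration_ms, "sharp_duration_ms")
  chk(sharp_amplitude_uv, "sharp_amplitude_uv")
  if (spike_duration_ms[2] > sharp_duration_ms[1])
    stop("spike and sharp duration intervals must be disjoint (spike right-open at the shared bound)")
  list(
    list(wave_class = "spike", duration_ms = spike_duration_ms,
         duration_hi_open = TRUE, amplitude_uv = spike_amplitude_uv),
    list(wave_class = "sharp", duration_ms = sharp_duration_ms,
         duration_hi_open = FALSE, amplitude_uv = sharp_amplitude_uv)
  )
}

#' Find candidate peaks with flanking troughs
#'
#' Locates every strict local maximum of the signal and, for each, the nearest
#' flanking troughs: walking outward from the peak while samples strictly
#' decrease; the walk stops at the first non-decrease (or at a window edge,
#' which counts as a trough so transients adjacent to window boundaries are
#' not lost).
#'
#' @param x Numeric vector (>= 3 samples).
#' @return Integer matrix with one row per peak and columns `left`, `peak`,
#'   `right` (1-based indices), sorted by peak position. Zero rows when the
#'   signal has no strict interior maximum.
#' @export
detect_candidate_peaks <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  core <- 2:(n - 1L)
  is_peak <- x[core] > x[core - 1L] & x[core] > x[core + 1L]
  peaks <- core[is_peak]
  out <- matrix(integer(0), ncol = 3L,
                dimnames = list(NULL, c("left", "peak", "right")))
  if (length(peaks) == 0L) return(out)
  triples <- t(vapply(peaks, function(p) {
    l <- p
    while (l > 1L && x[l - 1L] < x[l]) l <- l - 1L
    r <- p
    while (r < n && x[r + 1L] < x[r]) r <- r + 1L
    c(l, p, r)
  }, integer(3)))
  colnames(triples) <- c("left", "peak", "right")
  triples
}

#' Measure and classify one candidate peak
#'
#' Duration is trough-to-trough width in milliseconds; amplitude is the peak
#' value minus the mean of the two trough values (a prominence-like measure,
#' robust to baseline drift). The triple is assigned to the first criterion
#' whose duration and amplitude intervals both contain the measurements
#' (spike checked before sharp), or `NULL` when none matches.
#'
#' @param triple Integer vector `(left, peak, right)` of 1-based indices.
#' @param x Numeric signal vector containing the triple.
#' @param fs Sampling frequency in Hz (> 0).
#' @param criteria Criteria list from [wave_criteria()].
#' @return A list describing the accepted event (`wave_class`, `peak_index`,
#'   `left`, `right`, `duration_ms`, `amplitude_uv`, `energy_uv2`) or `NULL`.
#' @export
classify_and_measure <- function(triple, x, fs, criteria = wave_criteria()) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  l <- triple[[1]]; p <- triple[[2]]; r <- triple[[3]]
  stopifnot(l >= 1, r <= length(x), l < p, p < r)
  duration_ms <- (r - l) / fs * 1000
  amplitude <- x[p] - mean(c(x[l], x[r]))
  for (cr in criteria) {
    dur_ok <- duration_ms >= cr$duration_ms[1] &&
      (if (isTRUE(cr$duration_hi_open)) duration_ms < cr$duration_ms[2]
       else duration_ms <= cr$duration_ms[2])
    amp_ok <- amplitude >= cr$amplitude_uv[1] && amplitude <= cr$amplitude_uv[2]
    if (dur_ok && amp_ok) {
      return(list(wave_class = cr$wave_class, peak_index = p,
                  left = l, right = r, duration_ms = duration_ms,
                  amplitude_uv = amplitude,
                  energy_uv2 = sum(x[l:r]^2)))
    }
  }
  NULL
}

#' Detect pathological wave events in a signal
#'
#' Runs peak detection, classifies each candidate against the
#' duration-amplitude criteria and enforces same-class support disjointness:
#' when consecutive accepted events of one class share a boundary trough, the
#' later event's energy support starts one sample later (duration and
#' amplitude are still measured trough-to-trough). With `detect_negative`,
#' detection is additionally run on the sign-flipped signal so downward
#' transients are found; by default only upward peaks are considered.
#'
#' @param x Numeric signal vector (microvolts).
#' @param fs Sampling frequency in Hz.
#' @param criteria Criteria list from [wave_criteria()].
#' @param detect_negative Also detect downward transients (default FALSE).
#' @return data.frame with one row per accepted event: `wave_class`,
#'   `peak_index`, `left`, `right`, `support_left` (energy support start,
#'   equal to `left` except after a shared trough), `duration_ms`,
#'   `amplitude_uv`, `energy_uv2`, `polarity` (+1/-1).
#' @export
wave_events <- function(x, fs, criteria = wave_criteria(),
                        detect_negative = FALSE) {
  x <- as.numeric(x)
  one_pass <- function(sig, polarity) {
    if (length(sig) < 3L) return(NULL)
    triples <- detect_candidate_peaks(sig)
    evs <- list()
    last_right <- c(spike = 0L, sharp = 0L)
    for (i in seq_len(nrow(triples))) {
      ev <- classify_and_measure(triples[i, ], sig, fs, criteria)
      if (is.null(ev)) next
      support_left <- ev$left
      if (support_left <= last_right[[ev$wave_class]])
        support_left <- last_right[[ev$wave_class]] + 1L
      # energy uses the original (unflipped) sample values squared
      energy <- sum(x[support_left:ev$right]^2)
      last_right[[ev$wave_class]] <- ev$right
      evs[[length(evs) + 1L]] <- data.frame(
        wave_class = ev$wave_class, peak_index = ev$peak_index,
        left = ev$left, right = ev$right, support_left = support_left,
        duration_ms = ev$duration_ms, amplitude_uv = ev$amplitude_uv,
        energy_uv2 = energy, polarity = polarity,
        stringsAsFactors = FALSE)
    }
    if (length(evs)) do.call(rbind, evs) else NULL
  }
  res <- one_pass(x, 1L)
  if (isTRUE(detect_negative)) res <- rbind(res, one_pass(-x, -1L))
  if (is.null(res))
    res <- data.frame(wave_class = character(0), peak_index = integer(0),
                      left = integer(0), right = integer(0),
                      support_left = integer(0), duration_ms = numeric(0),
                      amplitude_uv = numeric(0), energy_uv2 = numeric(0),
                      polarity = integer(0), stringsAsFactors = FALSE)
  res[order(res$peak_index), , drop = FALSE]
}

#' Per-window pathological wave energy
#'
#' Accumulates the squared-sample energy of accepted spike and sharp-wave
#' events: for each class, the sum over accepted events of the sum of squared
#' sample values across the event's support.
#'
#' @inheritParams wave_events
#' @return Named list: `spike_energy`, `sharp_energy` (microvolts squared),
#'   `spike_count`, `sharp_count`.
#' @export
wave_energy <- function(x, fs, criteria = wave_criteria(),
                        detect_negative = FALSE) {
  ev <- wave_events(x, fs, criteria, detect_negative)
  list(
    spike_energy = sum(ev$energy_uv2[ev$wave_class == "spike"]),
    sharp_energy = sum(ev$energy_uv2[ev$wave_class == "sharp"]),
    spike_count = sum(ev$wave_class == "spike"),
    sharp_count = sum(ev$wave_class == "sharp")
  )
}
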