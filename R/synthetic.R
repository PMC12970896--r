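#' State profile for the synthetic EEG generator
#'
#' Describes one seizure state as colored-noise background, an optional
#' rhythmic oscillation, and Poisson-injected pathological transients. The
#' profiles encode the directional structure the detection method assumes:
#' ictal segments carry more and larger spike/sharp events and more regular
#' (lower-complexity) background than interictal ones, with preictal in
#' between. These are fixture parameters for testing the pipeline, not claims
#' about physiology.
#'
#' @param state State label, e.g. `"interictal"`, `"preictal"`, `"ictal"`.
#' @param spike_rate,sharp_rate Event rates in events per second.
#' @param spike_amplitude_uv,sharp_amplitude_uv Uniform amplitude ranges
#'   (microvolts) for injected events; keep them inside the corresponding
#'   [wave_criteria()] intervals when events are meant to be detectable.
#' @param spike_width_ms,sharp_width_ms Uniform trough-to-trough width ranges
#'   (ms).
#' @param noise_exponent Spectral exponent of the background (power
#'   proportional to `1/f^exponent`; 0 = white, 1 = pink).
#' @param amplitude_scale Background standard deviation in microvolts.
#' @param oscillation_freq Frequency (Hz) of the deterministic oscillation.
#' @param regularity Fraction of background variance carried by the
#'   oscillation, in `[0, 1]`; higher values lower both permutation entropy
#'   and fractal dimension.
#' @param regularity_jitter Half-range of the uniform per-recording jitter
#'   applied to `regularity` (clamped to `[0, 1]`). Recordings, not windows,
#'   differ in complexity — the inter-recording variability that makes
#'   recording-stratified evaluation necessary and that the wide, overlapping
#'   per-state complexity distributions of clinical EEG show.
#' @param freq_jitter Half-range (Hz) of the per-recording jitter on
#'   `oscillation_freq`.
#' @param scale_jitter Relative half-range of the per-recording jitter on
#'   `amplitude_scale` (0.2 means 80-120% of the nominal scale).
#' @return A list of class `state_profile`.
#' @export
state_profile <- function(state, spike_rate, sharp_rate,
                          spike_amplitude_uv = c(60, 150),
                          spike_width_ms = c(25, 65),
                          sharp_amplitude_uv = c(110, 190),
                          sharp_width_ms = c(80, 180),
                          noise_exponent = 1, amplitude_scale = 15,
                          oscillation_freq = 5, regularity = 0.2,
                          regularity_jitter = 0.2, freq_jitter = 2,
                          scale_jitter = 0.2) {
  stopifnot(spike_rate >= 0, sharp_rate >= 0,
            regularity >= 0, regularity <= 1,
            amplitude_scale >= 0, noise_exponent >= 0,
            regularity_jitter >= 0, freq_jitter >= 0,
            scale_jitter >= 0, scale_jitter < 1)
  structure(list(state = state, spike_rate = spike_rate, sharp_rate = sharp_rate,
                 spike_amplitude_uv = spike_amplitude_uv,
                 spike_width_ms = spike_width_ms,
                 sharp_amplitude_uv = sharp_amplitude_uv,
                 sharp_width_ms = sharp_width_ms,
                 noise_exponent = noise_exponent,
                 amplitude_scale = amplitude_scale,
                 oscillation_freq = oscillation_freq,
                 regularity = regularity,
                 regularity_jitter = regularity_jitter,
                 freq_jitter = freq_jitter,
                 scale_jitter = scale_jitter),
            class = "state_profile")
}

# one per-recording realization of a profile: recording-level heterogeneity
# in complexity, oscillation frequency and background scale
realize_profile <- function(profile) {
  profile$regularity <- min(1, max(0, profile$regularity +
    stats::runif(1, -profile$regularity_jitter, profile$regularity_jitter)))
  profile$oscillation_freq <- max(0.5, profile$oscillation_freq +
    stats::runif(1, -profile$freq_jitter, profile$freq_jitter))
  profile$amplitude_scale <- profile$amplitude_scale *
    stats::runif(1, 1 - profile$scale_jitter, 1 + profile$scale_jitter)
  profile
}

#' Default three-state profiles
#'
#' Interictal background is irregular with rare transients; preictal shows a
#' marked rise in transient rate and regularity; ictal has frequent,
#' larger-amplitude transients on a more regular, higher-amplitude
#' background. Sharp-wave rates equal the spike rate of each state.
#'
#' @return Named list of [state_profile()] objects
#'   (`interictal`, `preictal`, `ictal`).
#' @export
default_state_profiles <- function() {
  list(
    interictal = state_profile("interictal", spike_rate = 0.05,
                               sharp_rate = 0.05, regularity = 0.2),
    preictal = state_profile("preictal", spike_rate = 0.5, sharp_rate = 0.5,
                             regularity = 0.4),
    ictal = state_profile("ictal", spike_rate = 2, sharp_rate = 2,
                          spike_amplitude_uv = c(110, 180),
                          sharp_amplitude_uv = c(150, 200),
                          amplitude_scale = 30, regularity = 0.7)
  )
}

#' Generate colored-noise background with optional oscillation
#'
#' Gaussian noise spectrally shaped to power `1/f^exponent`, standardized,
#' mixed with a fixed-frequency sinusoid of random phase so that the
#' oscillation carries a `regularity` fraction of the variance, then scaled
#' to the profile's amplitude. Uses the current RNG state; seed with
#' `set.seed()` (or via `seed`) for reproducibility.
#'
#' @param n Number of samples (>= 1).
#' @param fs Sampling frequency in Hz.
#' @param profile A [state_profile()].
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` (microvolts).
#' @export
generate_background <- function(n, fs, profile, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (profile$amplitude_scale == 0) return(numeric(n))
  z <- stats::rnorm(n)
  if (profile$noise_exponent > 0 && n > 2L) {
    sp <- stats::fft(z)
    freq <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L))) * fs / n
    gain <- c(0, freq[-1L]^(-profile$noise_exponent / 2))
    z <- Re(stats::fft(sp * gain, inverse = TRUE)) / n
  }
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  r <- profile$regularity
  if (r > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    osc <- sqrt(2) * sin(2 * pi * profile$oscillation_freq * (seq_len(n) - 1L) / fs + phase)
    z <- sqrt(1 - r) * z + sqrt(r) * osc
  }
  profile$amplitude_scale * z
}

# raised-cosine (Hann) pulse on 0..L samples: zero-valued troughs at both
# ends, unique peak A at L/2 (L must be even)
hann_pulse <- function(L, A) A * 0.5 * (1 - cos(2 * pi * (0:L) / L))

# classify a (duration, amplitude) pair by the same interval rules the
# detector applies, for ground-truth labels
event_true_class <- function(duration_ms, amplitude_uv, criteria = wave_criteria()) {
  for (cr in criteria) {
    dur_ok <- duration_ms >= cr$duration_ms[1] &&
      (if (isTRUE(cr$duration_hi_open)) duration_ms < cr$duration_ms[2]
       else duration_ms <= cr$duration_ms[2])
    amp_ok <- amplitude_uv >= cr$amplitude_uv[1] && amplitude_uv <= cr$amplitude_uv[2]
    if (dur_ok && amp_ok) return(cr$wave_class)
  }
  "none"
}

#' Inject pathological transients into a background signal
#'
#' Adds raised-cosine (Hann) pulses at Poisson-distributed times with widths
#' and amplitudes drawn from the profile. Pulses are non-overlapping (with a
#' two-sample guard band, by rejection with bounded retries) and kept clear
#' of the signal edges. The returned log records, for each event, its
#' ground-truth class under the duration-amplitude rules, support, exact
#' trough-to-trough duration, peak amplitude, and the exact added energy
#' (the pulse's sum of squares, which equals the detector's measured energy
#' on a zero background).
#'
#' @param background Numeric signal vector (modified copy is returned).
#' @param fs Sampling frequency in Hz.
#' @param profile A [state_profile()].
#' @param seed Optional integer seed.
#' @param criteria Criteria used for ground-truth class labels.
#' @param max_retries Placement retries per event before erroring (the error
#'   indicates an infeasible event rate for the signal length).
#' @return List with `samples` (signal plus pulses) and `events` (data.frame:
#'   `wave_class`, `left`, `peak_index`, `right`, `duration_ms`,
#'   `amplitude_uv`, `energy_uv2`).
#' @export
inject_events <- function(background, fs, profile, seed = NULL,
                          criteria = wave_criteria(), max_retries = 100L) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(background)
  n <- length(x)
  T_s <- n / fs
  n_spike <- stats::rpois(1, profile$spike_rate * T_s)
  n_sharp <- stats::rpois(1, profile$sharp_rate * T_s)
  kinds <- c(rep("spike", n_spike), rep("sharp", n_sharp))
  occupied <- logical(n)
  logs <- list()
  for (kind in kinds) {
    wr <- if (kind == "spike") profile$spike_width_ms else profile$sharp_width_ms
    ar <- if (kind == "spike") profile$spike_amplitude_uv else profile$sharp_amplitude_uv
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      w_ms <- stats::runif(1, wr[1], wr[2])
      L <- max(4L, 2L * as.integer(round(w_ms * fs / 2000)))
      if (L + 4L >= n) next
      A <- stats::runif(1, ar[1], ar[2])
      s <- sample.int(n - L - 3L, 1L) + 1L   # support s .. s+L, >=1 sample from edges
      span <- max(1L, s - 2L):min(n, s + L + 2L)
      if (any(occupied[span])) next
      pulse <- hann_pulse(L, A)
      x[s:(s + L)] <- x[s:(s + L)] + pulse
      occupied[s:(s + L)] <- TRUE
      dur_ms <- L / fs * 1000
      logs[[length(logs) + 1L]] <- data.frame(
        wave_class = event_true_class(dur_ms, A, criteria),
        left = s, peak_index = s + L %/% 2L, right = s + L,
        duration_ms = dur_ms, amplitude_uv = A,
        energy_uv2 = sum(pulse^2), stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place a non-overlapping event after ", max_retries,
           " retries; event rate too high for the signal length")
  }
  events <- if (length(logs)) do.call(rbind, logs) else
    data.frame(wave_class = character(0), left = integer(0),
               peak_index = integer(0), right = integer(0),
               duration_ms = numeric(0), amplitude_uv = numeric(0),
               energy_uv2 = numeric(0), stringsAsFactors = FALSE)
  events <- events[order(events$peak_index), , drop = FALSE]
  rownames(events) <- NULL
  list(samples = x, events = events)
}

#' Generate a labeled synthetic EEG dataset
#'
#' Produces `n_per_state` recordings per state from the given profiles, each
#' with a ground-truth event log. Fully deterministic given `master_seed`:
#' two runs with the same seed produce bit-identical sample values. At the
#' default profiles the per-state feature means are ordered as the method
#' assumes: spike/sharp energy highest in ictal and lowest in interictal,
#' permutation entropy and fractal dimension lowest in ictal, preictal
#' intermediate.
#'
#' @param n_per_state Recordings per state (default 50).
#' @param duration_s Recording duration in seconds (default 23.6).
#' @param fs Sampling frequency in Hz (default 173.61).
#' @param profiles Named list of [state_profile()] objects
#'   (default [default_state_profiles()]).
#' @param master_seed Integer master seed (default 1).
#' @param criteria Criteria for ground-truth event labels.
#' @return Object of class `synth_eeg`: `recordings` (list of
#'   [recording()]), `event_logs` (named list of event data.frames),
#'   `profiles`, `master_seed`, `fs`, `duration_s`.
#' @export
generate_dataset <- function(n_per_state = 50, duration_s = 23.6, fs = 173.61,
                             profiles = default_state_profiles(),
                             master_seed = 1L, criteria = wave_criteria()) {
  set.seed(master_seed)
  n <- as.integer(round(duration_s * fs))
  recordings <- list()
  event_logs <- list()
  for (profile in profiles) {
    for (i in seq_len(n_per_state)) {
      id <- sprintf("%s_%03d", profile$state, i)
      prof_i <- realize_profile(profile)
      bg <- generate_background(n, fs, prof_i)
      inj <- inject_events(bg, fs, prof_i, criteria = criteria)
      recordings[[id]] <- recording(inj$samples, fs = fs, recording_id = id,
                                    label = profile$state)
      event_logs[[id]] <- inj$events
    }
  }
  structure(list(recordings = recordings, event_logs = event_logs,
                 profiles = profiles, master_seed = master_seed,
                 fs = fs, duration_s = duration_s),
            class = "synth_eeg")
}

#' @export
print.synth_eeg <- function(x, ...) {
  labs <- table(vapply(x$recordings, `[[`, character(1), "label"))
  cat(sprintf("<synth_eeg> %d recordings (%s), %.5g Hz, %.3g s, seed %d\n",
              length(x$recordings),
              paste(names(labs), labs, sep = ": ", collapse = ", "),
              x$fs, x$duration_s, x$master_seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' One plain-text file per recording (one sample per line) plus
#' `events.json` with the ground-truth event logs and `manifest.csv` mapping
#' file names to labels.
#'
#' @param dataset A `synth_eeg` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_eeg"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset$recordings)
    write_bonn_text(rec, file.path(dir, paste0(rec$recording_id, ".txt")))
  manifest <- data.frame(
    file = paste0(names(dataset$recordings), ".txt"),
    recording_id = names(dataset$recordings),
    label = vapply(dataset$recordings, `[[`, character(1), "label"),
    row.names = NULL)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$event_logs, file.path(dir, "events.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
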