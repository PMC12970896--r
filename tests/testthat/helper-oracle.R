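# Independent brute-force oracle for the wave detector: literal scans and
# rule applications, no shared code with the package implementation.

oracle_wave_events <- function(x, fs, spike_dur = c(20, 70), spike_amp = c(50, Inf),
                               sharp_dur = c(70, 200), sharp_amp = c(100, 200)) {
  n <- length(x)
  events <- list()
  last_right <- list(spike = 0, sharp = 0)
  for (p in seq_len(n)) {
    if (p == 1 || p == n) next
    if (!(x[p] > x[p - 1] && x[p] > x[p + 1])) next
    # literal outward walk while strictly decreasing
    l <- p
    repeat {
      if (l == 1) break
      if (x[l - 1] < x[l]) l <- l - 1 else break
    }
    r <- p
    repeat {
      if (r == n) break
      if (x[r + 1] < x[r]) r <- r + 1 else break
    }
    dur <- (r - l) / fs * 1000
    amp <- x[p] - (x[l] + x[r]) / 2
    cls <- NULL
    if (dur >= spike_dur[1] && dur < spike_dur[2] &&
        amp >= spike_amp[1] && amp <= spike_amp[2]) {
      cls <- "spike"
    } else if (dur >= sharp_dur[1] && dur <= sharp_dur[2] &&
               amp >= sharp_amp[1] && amp <= sharp_amp[2]) {
      cls <- "sharp"
    }
    if (is.null(cls)) next
    sl <- l
    if (sl <= last_right[[cls]]) sl <- last_right[[cls]] + 1
    last_right[[cls]] <- r
    events[[length(events) + 1]] <- data.frame(
      wave_class = cls, peak_index = as.integer(p), left = as.integer(l),
      right = as.integer(r), support_left = as.integer(sl),
      duration_ms = dur, amplitude_uv = amp,
      energy_uv2 = sum(x[sl:r]^2), stringsAsFactors = FALSE)
  }
  if (length(events)) do.call(rbind, events) else NULL
}

oracle_energy <- function(x, fs) {
  ev <- oracle_wave_events(x, fs)
  if (is.null(ev)) return(list(spike = 0, sharp = 0))
  list(spike = sum(ev$energy_uv2[ev$wave_class == "spike"]),
       sharp = sum(ev$energy_uv2[ev$wave_class == "sharp"]))
}

# a Hann-shaped test pulse embedded in zeros: trough-to-trough width L
# samples (even), peak amplitude A, support starting at index s
make_pulse_window <- function(n, s, L, A) {
  x <- numeric(n)
  x[s:(s + L)] <- A * 0.5 * (1 - cos(2 * pi * (0:L) / L))
  x
}
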