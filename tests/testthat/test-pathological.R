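test_that("candidate peak detection finds strict maxima with flanking troughs", {
  expect_equal(nrow(detect_candidate_peaks(rep(1, 10))), 0)
  expect_equal(nrow(detect_candidate_peaks(c(0, 1, 2, 3))), 0)
  tr <- detect_candidate_peaks(c(0, 1, 0, 2, 0))
  expect_equal(tr[, "peak"], c(2, 4))
  expect_equal(tr[, "left"], c(1, 3))
  expect_equal(tr[, "right"], c(3, 5))
  expect_error(detect_candidate_peaks(c(1, 2)), "3 samples")
})

test_that("duration-amplitude rules assign spike, sharp or nothing", {
  fs <- 200
  # 8 samples trough-to-trough = 40 ms, peak 120 over zero troughs -> spike
  x <- make_pulse_window(40, 10, 8, 120)
  tr <- detect_candidate_peaks(x)
  ev <- classify_and_measure(tr[1, ], x, fs)
  expect_equal(ev$wave_class, "spike")
  expect_equal(ev$duration_ms, 40)
  expect_equal(ev$amplitude_uv, 120)
  # stretched to 24 samples = 120 ms at 150 uV -> sharp
  x <- make_pulse_window(60, 10, 24, 150)
  ev <- classify_and_measure(detect_candidate_peaks(x)[1, ], x, fs)
  expect_equal(ev$wave_class, "sharp")
  expect_equal(ev$duration_ms, 120)
  # 30 uV spike-width pulse fails the amplitude bar
  x <- make_pulse_window(40, 10, 8, 30)
  expect_null(classify_and_measure(detect_candidate_peaks(x)[1, ], x, fs))
  expect_error(classify_and_measure(tr[1, ], x, fs = -1), "positive")
})

test_that("the 70 ms boundary belongs to sharp waves", {
  fs <- 200  # 14 samples = 70 ms exactly
  x <- make_pulse_window(60, 10, 14, 150)
  ev <- classify_and_measure(detect_candidate_peaks(x)[1, ], x, fs)
  expect_equal(ev$wave_class, "sharp")
})

test_that("wave energy accumulates squared samples over event supports", {
  fs <- 200
  expect_equal(wave_energy(rep(0, 64), fs),
               list(spike_energy = 0, sharp_energy = 0,
                    spike_count = 0, sharp_count = 0))
  # hand-summed fixture: support [0,30,60,90,120,90,60,30,0]
  x <- numeric(40); x[11:19] <- c(0, 30, 60, 90, 120, 90, 60, 30, 0)
  en <- wave_energy(x, fs)
  expect_equal(en$spike_energy, 39600)
  expect_equal(en$spike_count, 1)
  # one qualifying spike AND one qualifying sharp in the same window
  x <- make_pulse_window(120, 5, 8, 120) + make_pulse_window(120, 60, 24, 150)
  en <- wave_energy(x, fs)
  expect_equal(en$spike_count, 1)
  expect_equal(en$sharp_count, 1)
  or <- oracle_energy(x, fs)
  expect_equal(en$spike_energy, or$spike)
  expect_equal(en$sharp_energy, or$sharp)
})

test_that("energy is additive over identical non-overlapping spikes", {
  fs <- 200
  one <- make_pulse_window(300, 10, 8, 120)
  e1 <- wave_energy(one, fs)$spike_energy
  three <- make_pulse_window(300, 10, 8, 120) +
    make_pulse_window(300, 110, 8, 120) +
    make_pulse_window(300, 210, 8, 120)
  en <- wave_energy(three, fs)
  expect_equal(en$spike_count, 3)
  expect_equal(en$spike_energy, 3 * e1)
})

test_that("classification and energy are translation invariant", {
  fs <- 200
  base <- wave_energy(make_pulse_window(200, 20, 8, 120), fs)
  for (s in c(50, 101, 160)) {
    shifted <- wave_energy(make_pulse_window(200, s, 8, 120), fs)
    expect_equal(shifted, base)
  }
})

test_that("downward transients are only found with detect_negative", {
  fs <- 200
  x <- -make_pulse_window(60, 10, 8, 120)
  expect_equal(nrow(wave_events(x, fs)), 0)
  ev <- wave_events(x, fs, detect_negative = TRUE)
  expect_equal(ev$wave_class, "spike")
  expect_equal(ev$polarity, -1L)
  expect_equal(ev$amplitude_uv, 120)
})

test_that("detector matches the brute-force oracle on random short windows", {
  set.seed(99)
  fs <- 173.61
  for (i in 1:60) {
    n <- sample(16:64, 1)
    x <- cumsum(rnorm(n, sd = 40))          # drifting, trough-rich signal
    got <- wave_events(x, fs)
    want <- oracle_wave_events(x, fs)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$wave_class, want$wave_class)
      expect_equal(got$peak_index, want$peak_index)
      expect_equal(got$energy_uv2, want$energy_uv2)
    }
  }
})

test_that("same-class supports are disjoint", {
  set.seed(5)
  fs <- 173.61
  for (i in 1:40) {
    x <- cumsum(rnorm(64, sd = 50))
    ev <- wave_events(x, fs)
    for (cls in c("spike", "sharp")) {
      sub <- ev[ev$wave_class == cls, ]
      if (nrow(sub) < 2) next
      covered <- unlist(mapply(seq, sub$support_left, sub$right))
      expect_false(anyDuplicated(covered) > 0)
    }
  }
})

test_that("criteria constructor validates interval structure", {
  expect_error(wave_criteria(spike_duration_ms = c(70, 20)), "increasing")
  expect_error(wave_criteria(spike_duration_ms = c(20, 80)), "disjoint")
  crit <- wave_criteria(sharp_amplitude_uv = c(100, Inf))
  expect_equal(crit[[2]]$amplitude_uv[2], Inf)
})
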