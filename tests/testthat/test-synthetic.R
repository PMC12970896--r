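test_that("background generator hits its limiting behaviours", {
  prof <- state_profile("x", 0, 0, regularity = 0, noise_exponent = 0)
  expect_identical(generate_background(100, 200,
                                       state_profile("x", 0, 0, amplitude_scale = 0)),
                   numeric(100))
  # flat-spectrum background behaves like white noise
  bg <- generate_background(1024, 173.61, prof, seed = 61)
  expect_equal(higuchi_fd(bg), 2, tolerance = 0.1)
  # pure oscillation: permutation entropy near its regular-signal floor
  prof_sine <- state_profile("x", 0, 0, regularity = 1)
  sine <- generate_background(1024, 173.61, prof_sine, seed = 61)
  # a sampled sine spends most of its time in the two monotone patterns,
  # well below the noise entropy though not at the 2-pattern floor
  expect_lt(permutation_entropy(sine, m = 3),
            0.7 * permutation_entropy(bg, m = 3))
  # seeded determinism
  expect_identical(generate_background(256, 200, prof, seed = 5),
                   generate_background(256, 200, prof, seed = 5))
})

test_that("event injection at rate zero is a no-op with an empty log", {
  bg <- numeric(512)
  prof <- state_profile("x", 0, 0)
  out <- inject_events(bg, 200, prof, seed = 1)
  expect_identical(out$samples, bg)
  expect_equal(nrow(out$events), 0)
})

test_that("a single injected pulse is recovered exactly by the detector", {
  prof <- state_profile("x", spike_rate = 0, sharp_rate = 0, amplitude_scale = 0)
  # place one 40 ms / 120 uV pulse by hand through the same pulse shape
  fs <- 200
  x <- make_pulse_window(1024, 300, 8, 120)
  ev <- wave_events(x, fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$wave_class, "spike")
  expect_equal(ev$energy_uv2, sum(x^2))
})

test_that("injected event counts follow the Poisson law", {
  prof <- state_profile("x", spike_rate = 0.5, sharp_rate = 0.5,
                        amplitude_scale = 0)
  fs <- 173.61
  n <- 4096
  T_s <- n / fs
  counts <- vapply(1:40, function(s) {
    nrow(inject_events(numeric(n), fs, prof, seed = 100 + s)$events)
  }, numeric(1))
  lambda <- 1.0 * T_s
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 40))
})

test_that("infeasible event rates error after bounded retries", {
  prof <- state_profile("x", spike_rate = 40, sharp_rate = 0,
                        amplitude_scale = 0)
  expect_error(inject_events(numeric(300), 173.61, prof, seed = 2,
                             max_retries = 10),
               "retries")
})

test_that("datasets are seed-deterministic and respect n_per_state", {
  ds1 <- generate_dataset(n_per_state = 2, duration_s = 3, fs = 173.61,
                          master_seed = 71)
  ds2 <- generate_dataset(n_per_state = 2, duration_s = 3, fs = 173.61,
                          master_seed = 71)
  expect_identical(lapply(ds1$recordings, `[[`, "samples"),
                   lapply(ds2$recordings, `[[`, "samples"))
  expect_equal(length(ds1$recordings), 6)
  ds3 <- generate_dataset(n_per_state = 2, duration_s = 3, fs = 173.61,
                          master_seed = 72)
  expect_false(identical(ds1$recordings[[1]]$samples,
                         ds3$recordings[[1]]$samples))
  expect_equal(length(generate_dataset(n_per_state = 0)$recordings), 0)
})

test_that("per-state feature means are ordered as the method assumes", {
  for (s in c(3, 14, 159, 2653, 58979)) {
    ds <- generate_dataset(n_per_state = 8, duration_s = 8, master_seed = s)
    feats <- extract_features(ds)
    mu <- aggregate(feats[c("SpikeE", "SharpE", "HFD", "PE")],
                    by = feats["label"], FUN = mean)
    rownames(mu) <- mu$label
    expect_gt(mu["ictal", "SpikeE"], mu["preictal", "SpikeE"])
    expect_gt(mu["preictal", "SpikeE"], mu["interictal", "SpikeE"])
    expect_gt(mu["ictal", "SharpE"], mu["interictal", "SharpE"])
    expect_lt(mu["ictal", "PE"], mu["interictal", "PE"])
    expect_lt(mu["ictal", "HFD"], mu["interictal", "HFD"])
    expect_lt(mu["ictal", "PE"], mu["preictal", "PE"])
  }
})

test_that("datasets round-trip through the text format with ground truth", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(n_per_state = 1, duration_s = 3, master_seed = 81)
  write_dataset(ds, dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 3)
  rec <- ds$recordings[[1]]
  back <- read_bonn_text(file.path(dir, paste0(rec$recording_id, ".txt")),
                         fs = ds$fs, warn_calibration = FALSE)
  expect_equal(back$samples, rec$samples, tolerance = 1e-10)
  logs <- jsonlite::read_json(file.path(dir, "events.json"),
                              simplifyVector = TRUE)
  expect_equal(names(logs), names(ds$recordings))
})
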