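test_that("default profiles encode the documented class orderings", {
  for (preset in c("paper", "desk")) {
    p <- default_profiles(preset)
    expect_setequal(p$class, wear_classes())
    expect_equal(nrow(p), 5)
    g <- function(cl, col) p[[col]][p$class == cl]
    expect_lt(g("adhesive", "amplitude_scale"),
              g("abrasive", "amplitude_scale"))
    expect_gt(g("burnishing", "burst_rate"), g("abrasive", "burst_rate"))
    expect_gt(g("burnishing_to_scratching", "amplitude_scale"),
              g("burnishing", "amplitude_scale"))
    expect_gt(g("scratching", "amplitude_scale"),
              g("burnishing_to_scratching", "amplitude_scale"))
    # adhesive is the smoother signature: tonal carrier, narrower band
    expect_identical(g("adhesive", "carrier_kind"), "tonal")
    expect_lt(g("adhesive", "carrier_high") - g("adhesive", "carrier_low"),
              g("abrasive", "carrier_high") - g("abrasive", "carrier_low"))
  }
})

test_that("class_profile validates its invariants", {
  expect_error(class_profile(10, rise_tau = 1e-3, decay_tau = 1e-4,
                             carrier_low = 1e3, carrier_high = 2e3),
               "rise_tau")
  expect_error(class_profile(10, rise_tau = 1e-4, decay_tau = 1e-3,
                             carrier_low = 2e3, carrier_high = 1e3),
               "carrier")
  expect_error(class_profile(10, timing_jitter = 1, rise_tau = 1e-4,
                             decay_tau = 1e-3, carrier_low = 1e3,
                             carrier_high = 2e3),
               "jitter")
})

silent_profile <- function(noise = 0) {
  class_profile(burst_rate = 0, amplitude_scale = 1, rise_tau = 1e-4,
                decay_tau = 1e-3, carrier_low = 1e4, carrier_high = 4e4,
                noise_sigma = noise)
}

test_that("no sources and no noise yields the all-zero signal", {
  sig <- simulate_signal("abrasive", silent_profile(),
                         instrument_response(preset = "desk"),
                         duration = 0.01, fs = 2e5, seed = 1)
  expect_equal(length(sig$samples), 2000)
  expect_true(all(sig$samples == 0))
})

test_that("simulate_signal validates duration and carrier band", {
  prof <- default_profiles("desk")[1, ]
  resp <- instrument_response(preset = "desk")
  expect_error(simulate_signal("abrasive", prof, resp, -1, 2e5, 1),
               "duration")
  expect_error(simulate_signal("abrasive", prof, resp, 0.01, 2e4, 1),
               "carrier")
})

test_that("fixed seed reproduces samples bit-for-bit", {
  prof <- default_profiles("desk")[3, ]
  resp <- instrument_response(preset = "desk")
  a <- simulate_signal("burnishing", prof, resp, 0.01, 2e5, 99)
  b <- simulate_signal("burnishing", prof, resp, 0.01, 2e5, 99)
  expect_identical(a$samples, b$samples)
  c <- simulate_signal("burnishing", prof, resp, 0.01, 2e5, 100)
  expect_false(identical(a$samples, c$samples))
})

test_that("poisson event counts follow the rate", {
  prof <- class_profile(burst_rate = 100, amplitude_scale = 1,
                        rise_tau = 5e-5, decay_tau = 3e-4,
                        carrier_low = 1e4, carrier_high = 4e4)
  resp <- instrument_response(preset = "desk")
  counts <- vapply(1:200, function(s) {
    sig <- simulate_signal("abrasive", prof, resp, 0.1, 2e5, s)
    length(attr(sig, "event_times"))
  }, numeric(1))
  # Poisson(10) over 200 runs: SE of the mean is sqrt(10/200)
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 200))
})

test_that("instrument stage is linear: doubling amplitudes doubles output", {
  prof <- default_profiles("desk")[1, ]
  prof$noise_sigma <- 0
  prof2 <- prof
  prof2$amplitude_scale <- 2 * prof$amplitude_scale
  resp <- instrument_response(preset = "desk")
  a <- simulate_signal("abrasive", prof, resp, 0.01, 2e5, 5)
  b <- simulate_signal("abrasive", prof2, resp, 0.01, 2e5, 5)
  expect_equal(b$samples, 2 * a$samples, tolerance = 1e-12)
})

test_that("output power concentrates around the carrier band", {
  resp <- instrument_response(preset = "desk")
  for (cl in wear_classes()) {
    prof <- default_profiles("desk")[default_profiles("desk")$class == cl, ]
    prof$noise_sigma <- 0
    sig <- simulate_signal(cl, prof, resp, 0.02, 2e5, 11)
    spec <- Mod(fft(sig$samples))^2
    n <- length(spec)
    freq <- (0:(n - 1)) / n * 2e5
    half <- freq <= 1e5
    inband <- half & freq >= 0.5 * prof$carrier_low &
      freq <= 1.5 * prof$carrier_high
    expect_gt(sum(spec[inband]) / sum(spec[half]), 0.8)
  }
})

test_that("median window RMS follows the burnishing-family severity order", {
  profs <- default_profiles("desk")
  resp <- instrument_response(preset = "desk")
  med_rms <- function(cl) {
    prof <- profs[profs$class == cl, ]
    prof$noise_sigma <- 0
    vals <- vapply(1:20, function(s) {
      sig <- simulate_signal(cl, prof, resp, 0.02, 2e5, s)
      sqrt(mean(sig$samples^2))
    }, numeric(1))
    median(vals)
  }
  r <- vapply(c("burnishing", "burnishing_to_scratching", "scratching"),
              med_rms, numeric(1))
  expect_true(r["scratching"] > r["burnishing_to_scratching"])
  expect_true(r["burnishing_to_scratching"] > r["burnishing"])
})

test_that("simulate_dataset is balanced, seeded and reproducible", {
  expect_error(simulate_dataset(0, 0.01, preset = "desk"), "n_per_class")
  ds <- simulate_dataset(4, 0.005, seed = 21, preset = "desk")
  expect_equal(nrow(ds), 20)
  expect_true(all(table(ds$class) == 4))
  ds2 <- simulate_dataset(4, 0.005, seed = 21, preset = "desk")
  expect_identical(purrr::map(ds$signal, "samples"),
                   purrr::map(ds2$signal, "samples"))
  ds3 <- simulate_dataset(4, 0.005, seed = 22, preset = "desk")
  expect_false(identical(purrr::map(ds$signal, "samples"),
                         purrr::map(ds3$signal, "samples")))
})

test_that("difficulty scales only the noise floor", {
  sim <- function(d) simulate_dataset(1, 0.005, seed = 5, preset = "desk",
                                      difficulty = d)
  quiet <- sim(0)
  noisy1 <- sim(1)
  noisy2 <- sim(2)
  # same events, different noise floor: the residual is band-limited noise
  # whose amplitude is proportional to the difficulty scalar
  d1 <- noisy1$signal[[1]]$samples - quiet$signal[[1]]$samples
  d2 <- noisy2$signal[[1]]$samples - quiet$signal[[1]]$samples
  expect_gt(sd(d1), 0)
  expect_equal(sd(d2) / sd(d1), 2, tolerance = 1e-6)
  expect_error(simulate_dataset(1, 0.005, difficulty = -1), "difficulty")
})

test_that("datasets round-trip through text files and a manifest", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(1, 0.002, seed = 9, preset = "desk")
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_setequal(manifest$class, wear_classes())
  back <- read_ae_signal(file.path(dir, manifest$path[1]),
                         manifest$fs_hz[1])
  expect_equal(back$samples, ds$signal[[1]]$samples, tolerance = 1e-15)
})
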