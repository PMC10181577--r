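#' Construct an AE signal
#'
#' A thin container for a finite, real-valued voltage trace with its sampling
#' rate.
#'
#' @param samples Numeric vector of voltages; all values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `ae_signal`: a list with elements `samples` and
#'   `fs`.
#' @export
ae_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) abort("An AE signal needs at least one sample.")
  if (!all(is.finite(samples))) abort("All samples must be finite.")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  structure(list(samples = samples, fs = fs), class = "ae_signal")
}

#' @export
print.ae_signal <- function(x, ...) {
  cat(sprintf("<ae_signal: %d samples @ %g Hz (%.4g s), RMS %.4g V>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.ae_signal <- function(x) length(x$samples)

# FFT-based linear convolution, truncated to the length of x.
conv_trunc <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- 2^ceiling(log2(n))
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
                fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_along(x)]
}

# Render one burst: asymmetric-exponential envelope x band-limited carrier,
# unit peak envelope and unit-RMS carrier, so the event amplitude is the
# approximate burst peak.
render_burst <- function(profile, fs) {
  nb <- max(16, ceiling(fs * (2 * profile$rise_tau + 6 * profile$decay_tau)))
  t <- (0:(nb - 1)) / fs
  env <- (1 - exp(-t / profile$rise_tau)) * exp(-t / profile$decay_tau)
  env <- env / max(env)
  if (profile$carrier_kind == "tonal") {
    f0 <- (profile$carrier_low + profile$carrier_high) / 2
    phase <- runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * f0 * t + phase)
  } else {
    bf <- signal::butter(4, c(profile$carrier_low, profile$carrier_high) /
                              (fs / 2), type = "pass")
    carrier <- signal::filter(bf, rnorm(nb))
    carrier <- as.numeric(carrier)
  }
  crms <- sqrt(mean(carrier^2))
  if (crms > 0) carrier <- carrier / crms
  env * carrier
}

# Draw event times in [0, duration) under the profile's timing model.
draw_event_times <- function(profile, duration) {
  if (profile$burst_rate <= 0) return(numeric(0))
  if (profile$timing_model == "poisson") {
    n <- rpois(1, profile$burst_rate * duration)
    sort(runif(n, 0, duration))
  } else {
    period <- 1 / profile$burst_rate
    centres <- seq(period / 2, duration, by = period)
    jit <- runif(length(centres), -0.5, 0.5) * profile$timing_jitter * period
    pmin(pmax(centres + jit, 0), duration - 1e-12)
  }
}

#' Simulate one AE recording for a wear class
#'
#' Implements the source–path–instrument signal chain: an event train is drawn
#' (Poisson or jittered-periodic), each event is rendered as an
#' asymmetric-exponential envelope times a band-limited carrier, events are
#' superposed, the result is convolved with the lumped instrument impulse
#' response, and Gaussian sensor noise is added.
#'
#' @param class Wear-class label attached to the signal (see
#'   [wear_classes()]); purely metadata.
#' @param profile A [class_profile()] (or one row of [default_profiles()]).
#' @param response An [instrument_response()].
#' @param duration Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz; the carrier band must lie below `fs / 2`.
#' @param seed Integer seed; the output is bit-reproducible given
#'   `(seed, profile, response, duration, fs)`.
#'
#' @return An [ae_signal()] with attributes `class` and `event_times`
#'   (seconds).
#' @export
#' @examples
#' prof <- default_profiles("desk")
#' sig <- simulate_signal("abrasive", prof[prof$class == "abrasive", ],
#'                        instrument_response(preset = "desk"),
#'                        duration = 0.01, fs = 2e5, seed = 1)
#' sig
simulate_signal <- function(class, profile, response, duration, fs, seed) {
  if (duration <= 0) abort("`duration` must be positive.")
  n <- round(duration * fs)
  if (n < 1) abort("`duration * fs` must be at least 1 sample.")
  if (profile$carrier_high >= fs / 2) {
    abort("Invalid profile: carrier band must lie inside (0, fs/2).")
  }
  samples <- withr::with_seed(seed, {
    x <- numeric(n)
    times <- draw_event_times(profile, duration)
    for (t0 in times) {
      amp <- profile$amplitude_scale *
        exp(profile$amplitude_dispersion * rnorm(1) -
              profile$amplitude_dispersion^2 / 2)
      burst <- amp * render_burst(profile, fs)
      i0 <- floor(t0 * fs) + 1L
      idx <- i0:min(n, i0 + length(burst) - 1L)
      if (idx[1] <= n) x[idx] <- x[idx] + burst[seq_along(idx)]
    }
    if (length(times) > 0 || profile$noise_sigma > 0) {
      x <- conv_trunc(x, impulse_response(response, fs))
      if (profile$noise_sigma > 0) {
        x <- x + rnorm(n, 0, profile$noise_sigma)
      }
      # acquisition bandpass: conditions signal and noise alike before
      # digitisation, so recorded energy concentrates in the AE band
      if (!is.null(response$passband) && length(response$passband) == 2) {
        bp <- signal::butter(4, pmin(response$passband / (fs / 2), 0.999),
                             type = "pass")
        x <- as.numeric(signal::filter(bp, x))
      }
    }
    attr(x, "event_times") <- times
    x
  })
  out <- ae_signal(as.numeric(samples), fs)
  attr(out, "class_label") <- class
  attr(out, "event_times") <- attr(samples, "event_times")
  out
}

#' Simulate a balanced labelled dataset of AE recordings
#'
#' Generates `n_per_class` recordings for each of the five wear classes using
#' one profile set and instrument response. Per-record seeds are drawn
#' deterministically from the master seed, so the whole dataset is
#' bit-reproducible.
#'
#' @param n_per_class Recordings per class (>= 1).
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz; defaults to the preset's rate (2 MHz for
#'   `"paper"`, 200 kHz for `"desk"`).
#' @param seed Master integer seed.
#' @param preset Profile/instrument preset, see [default_profiles()].
#' @param profiles Profile table (one row per class); defaults to
#'   [default_profiles()] for `preset`.
#' @param response [instrument_response()]; defaults to the preset's sensor.
#' @param difficulty Non-negative scalar multiplying every profile's
#'   `noise_sigma`: 0 gives noise-free, cleanly separable classes; 1 (the
#'   default) is the nominal noise floor; larger values degrade class
#'   separability.
#'
#' @return A tibble of class `ae_dataset` with columns `signal_id`, `class`
#'   (factor over [wear_classes()]), `seed`, `signal` (list of
#'   [ae_signal()]); attributes record the profile snapshot, master seed,
#'   difficulty, `fs` and `duration`.
#' @export
#' @examples
#' ds <- simulate_dataset(2, duration = 0.005, seed = 7, preset = "desk")
#' ds
simulate_dataset <- function(n_per_class, duration, fs = NULL, seed = 1,
                             preset = c("paper", "desk"),
                             profiles = default_profiles(preset),
                             response = instrument_response(preset = preset),
                             difficulty = 1) {
  preset <- match.arg(preset)
  if (n_per_class < 1) abort("`n_per_class` must be >= 1.")
  if (difficulty < 0) abort("`difficulty` must be >= 0.")
  if (is.null(fs)) fs <- if (preset == "desk") 2e5 else 2e6
  classes <- profiles$class
  grid <- tidyr::expand_grid(class = classes, rep = seq_len(n_per_class))
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max, nrow(grid)))
  signals <- purrr::map(seq_len(nrow(grid)), function(i) {
    prof <- profiles[profiles$class == grid$class[i], ]
    prof$noise_sigma <- prof$noise_sigma * difficulty
    simulate_signal(grid$class[i], prof, response, duration, fs, seeds[i])
  })
  out <- tibble(
    signal_id = sprintf("%s_%02d", grid$class, grid$rep),
    class = factor(grid$class, levels = classes),
    seed = seeds,
    signal = signals
  )
  attr(out, "profiles") <- profiles
  attr(out, "master_seed") <- seed
  attr(out, "difficulty") <- difficulty
  attr(out, "fs") <- fs
  attr(out, "duration") <- duration
  class(out) <- c("ae_dataset", class(out))
  out
}

#' Write a dataset to disk as plain-text sample files plus a manifest
#'
#' Each recording is written as a single-column text file of voltages, and
#' `manifest.csv` maps `path`, `class`, `seed`, `duration_s`, `fs_hz`.
#'
#' @param dataset An `ae_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest tibble.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(dataset$signal_id, ".txt"))
  purrr::walk2(dataset$signal, paths, function(sig, p) {
    readr::write_lines(format(sig$samples, digits = 17, trim = TRUE,
                              scientific = TRUE), p)
  })
  manifest <- tibble(
    path = basename(paths),
    class = as.character(dataset$class),
    seed = dataset$seed,
    duration_s = purrr::map_dbl(dataset$signal, ~ length(.x$samples) / .x$fs),
    fs_hz = purrr::map_dbl(dataset$signal, "fs")
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read an AE signal from a delimited text file
#'
#' @param path File with one voltage sample per line.
#' @param fs Sampling rate in Hz.
#' @return An [ae_signal()].
#' @export
read_ae_signal <- function(path, fs) {
  ae_signal(as.numeric(readr::read_lines(path)), fs)
}
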