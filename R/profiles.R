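#' The five joint-wear classes
#'
#' AE signatures are modelled for five tribological wear regimes of an
#' articulating joint: abrasive (scratch/rub), adhesive (plastic-contact
#' bonding and fracture), burnishing (sliding-induced smoothing),
#' burnishing-to-scratching (transitional regime) and scratching (advanced
#' abrasion/ploughing).
#'
#' @return Character vector of the five class labels, in severity order for
#'   the burnishing family.
#' @export
#' @examples
#' wear_classes()
wear_classes <- function() {
  c("abrasive", "adhesive", "burnishing", "burnishing_to_scratching",
    "scratching")
}

#' Generative profile for one wear class
#'
#' A `class_profile` holds the parameters of the burst-train source model for
#' one wear regime: how often AE events fire, how their timing is drawn, how
#' large and variable they are, the rise/decay shape of the burst envelope,
#' the carrier band the burst energy occupies, and the additive sensor noise
#' floor.
#'
#' @param burst_rate Events per second (>= 0; 0 means a silent source).
#' @param timing_model `"poisson"` (memoryless event train) or `"periodic"`
#'   (jittered regular train, the "many cyclical envelopes" pattern).
#' @param timing_jitter For periodic timing, jitter as a fraction of the mean
#'   inter-event interval, in `[0, 1)`.
#' @param amplitude_scale Dimensionless event amplitude scale (> 0).
#' @param amplitude_dispersion Log-normal sigma of per-event amplitude (>= 0).
#' @param rise_tau,decay_tau Envelope rise and decay time constants in
#'   seconds; AE bursts show a fast rise, a peak, then a transient decay, so
#'   `rise_tau < decay_tau` is required.
#' @param carrier_low,carrier_high Carrier band edges in Hz.
#' @param carrier_kind `"broadband_noise"` (band-limited noise carrier,
#'   "rough" bursts) or `"tonal"` (fixed-frequency carrier, smoother bursts).
#' @param noise_sigma Additive Gaussian sensor-noise SD in volts (>= 0).
#'
#' @return A one-row tibble of class `class_profile`.
#' @export
class_profile <- function(burst_rate, timing_model = c("poisson", "periodic"),
                          timing_jitter = 0, amplitude_scale = 1,
                          amplitude_dispersion = 0.3,
                          rise_tau, decay_tau,
                          carrier_low, carrier_high,
                          carrier_kind = c("broadband_noise", "tonal"),
                          noise_sigma = 0) {
  timing_model <- match.arg(timing_model)
  carrier_kind <- match.arg(carrier_kind)
  if (burst_rate < 0) abort("`burst_rate` must be >= 0.")
  if (timing_jitter < 0 || timing_jitter >= 1) {
    abort("`timing_jitter` must lie in [0, 1).")
  }
  if (burst_rate > 0 && amplitude_scale <= 0) {
    abort("`amplitude_scale` must be > 0.")
  }
  if (amplitude_dispersion < 0) abort("`amplitude_dispersion` must be >= 0.")
  if (rise_tau <= 0 || decay_tau <= 0 || rise_tau >= decay_tau) {
    abort("Need 0 < rise_tau < decay_tau (rise, peak, transient decay).")
  }
  if (carrier_low <= 0 || carrier_high <= carrier_low) {
    abort("Need 0 < carrier_low < carrier_high.")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  out <- tibble(
    burst_rate = burst_rate, timing_model = timing_model,
    timing_jitter = timing_jitter, amplitude_scale = amplitude_scale,
    amplitude_dispersion = amplitude_dispersion,
    rise_tau = rise_tau, decay_tau = decay_tau,
    carrier_low = carrier_low, carrier_high = carrier_high,
    carrier_kind = carrier_kind, noise_sigma = noise_sigma
  )
  class(out) <- c("class_profile", class(out))
  out
}

#' Default generative profiles for the five wear classes
#'
#' The defaults encode the qualitative phenomenology of the five wear
#' signatures: abrasive and adhesive wear show sparse enveloped bursts, with
#' adhesive clearly lower in amplitude and smoother (tonal carrier);
#' burnishing shows many cyclical envelopes per time frame (a fast, jittered
#' periodic train of narrowband bursts, as expected from smooth-surface
#' sliding); burnishing-to-scratching repeats that pattern at slightly higher
#' amplitude and carrier frequency; scratching shows dense broadband activity
#' at much more intense amplitude. Classes therefore differ chiefly in
#' carrier band and burst rate, with the amplitude orderings listed above.
#' Only the orderings are constrained by the phenomenology — the concrete
#' numbers are package defaults, kept in this one registry and overridable by
#' passing edited profiles to [simulate_signal()] / [simulate_dataset()].
#'
#' @param preset `"paper"`: 2 MHz sampling with carrier energy in the
#'   100–600 kHz AE band. `"desk"`: all frequencies (sampling rate, carrier
#'   bands, sensor resonance) divided by 10 while burst envelopes keep their
#'   physical time constants, preserving the temporal burst structure at a
#'   tenth of the sample count; intended for fast experimentation and tests.
#'
#' @return A tibble with one row per wear class (column `class`) and the
#'   [class_profile()] columns.
#' @export
#' @examples
#' default_profiles()
default_profiles <- function(preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  fscale <- if (preset == "desk") 0.1 else 1
  row <- function(class, ...) {
    p <- class_profile(...)
    dplyr::bind_cols(tibble(class = class), p)
  }
  dplyr::bind_rows(
    row("abrasive",
        burst_rate = 800, timing_model = "periodic", timing_jitter = 0.45,
        amplitude_scale = 1.0, amplitude_dispersion = 0.2,
        rise_tau = 20e-6, decay_tau = 150e-6,
        carrier_low = 100e3 * fscale, carrier_high = 600e3 * fscale,
        carrier_kind = "broadband_noise", noise_sigma = 0.05),
    row("adhesive",
        burst_rate = 800, timing_model = "periodic", timing_jitter = 0.45,
        amplitude_scale = 0.45, amplitude_dispersion = 0.2,
        rise_tau = 30e-6, decay_tau = 200e-6,
        carrier_low = 150e3 * fscale, carrier_high = 350e3 * fscale,
        carrier_kind = "tonal", noise_sigma = 0.05),
    row("burnishing",
        burst_rate = 1500, timing_model = "periodic", timing_jitter = 0.15,
        amplitude_scale = 0.5, amplitude_dispersion = 0.2,
        rise_tau = 15e-6, decay_tau = 80e-6,
        carrier_low = 110e3 * fscale, carrier_high = 200e3 * fscale,
        carrier_kind = "tonal", noise_sigma = 0.05),
    row("burnishing_to_scratching",
        burst_rate = 1500, timing_model = "periodic", timing_jitter = 0.2,
        amplitude_scale = 0.8, amplitude_dispersion = 0.2,
        rise_tau = 15e-6, decay_tau = 80e-6,
        carrier_low = 160e3 * fscale, carrier_high = 300e3 * fscale,
        carrier_kind = "tonal", noise_sigma = 0.05),
    row("scratching",
        burst_rate = 2500, timing_model = "poisson",
        amplitude_scale = 2.0, amplitude_dispersion = 0.25,
        rise_tau = 10e-6, decay_tau = 60e-6,
        carrier_low = 250e3 * fscale, carrier_high = 600e3 * fscale,
        carrier_kind = "broadband_noise", noise_sigma = 0.05)
  )
}

#' Lumped instrument response (propagation medium + acquisition chain)
#'
#' The measured voltage is the source burst train passed through the tissue
#' path and the acquisition chain. The linear stages are lumped into a
#' unit-peak-gain second-order resonator (a moderately broadband resonant
#' piezoelectric AE sensor) followed by the acquisition bandpass filter,
#' which conditions everything reaching the digitiser — including the sensor
#' and preamplifier noise floor — to the AE band (100–600 kHz at the paper
#' preset).
#'
#' @param resonant_freq Resonance in Hz.
#' @param damping_ratio Dimensionless damping in (0, 1).
#' @param gain Peak frequency-response gain (dimensionless).
#' @param passband Acquisition bandpass edges in Hz (`c(low, high)`), or
#'   `NULL` to disable the bandpass stage.
#' @param preset Convenience preset matching [default_profiles()]:
#'   `"paper"` = 300 kHz resonance with a 100–600 kHz bandpass, `"desk"` =
#'   both divided by 10; damping 0.2.
#'
#' @return A list of class `instrument_response`.
#' @export
instrument_response <- function(resonant_freq = NULL, damping_ratio = 0.2,
                                gain = 1, passband = NULL,
                                preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  fscale <- if (preset == "desk") 0.1 else 1
  if (is.null(resonant_freq)) resonant_freq <- 300e3 * fscale
  if (is.null(passband)) passband <- c(100e3, 600e3) * fscale
  if (resonant_freq <= 0) abort("`resonant_freq` must be > 0.")
  if (damping_ratio <= 0 || damping_ratio >= 1) {
    abort("`damping_ratio` must lie in (0, 1).")
  }
  if (length(passband) == 2 &&
      (passband[1] <= 0 || passband[2] <= passband[1])) {
    abort("`passband` must satisfy 0 < low < high.")
  }
  structure(
    list(resonant_freq = resonant_freq, damping_ratio = damping_ratio,
         gain = gain, passband = passband),
    class = "instrument_response"
  )
}

# Impulse response of the resonator, sampled at fs, truncated where the
# envelope falls below 1% of its peak, and normalised to unit peak
# frequency-response gain (times `gain`).
impulse_response <- function(response, fs) {
  w0 <- 2 * pi * response$resonant_freq
  zeta <- response$damping_ratio
  if (response$resonant_freq >= fs / 2) {
    abort("Instrument resonance must lie below the Nyquist frequency.")
  }
  r <- exp(-zeta * w0 / fs)
  n_tail <- ceiling(log(0.01) / log(r))
  n <- 0:n_tail
  theta <- w0 * sqrt(1 - zeta^2) / fs
  h <- r^n * sin(theta * n)
  nfft <- 2^ceiling(log2(4 * length(h)))
  peak <- max(Mod(fft(c(h, numeric(nfft - length(h))))))
  h * response$gain / peak
}
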