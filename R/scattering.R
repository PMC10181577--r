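#' Configuration of the deep wavelet scattering network
#'
#' A two-order scattering network: cascaded wavelet convolution, complex
#' modulus and low-pass averaging with preset (untrained) Gabor filters.
#' Defaults follow the study configuration: two orders, an invariance scale
#' of 1 s, and filter banks with 8 wavelets per octave (first order) and 1
#' wavelet per octave (second order).
#'
#' @param n_orders Number of scattering orders, 1 or 2.
#' @param invariance_scale Nominal time support `T` of the averaging low-pass
#'   filter, in seconds. When `T` exceeds the analysed window the support is
#'   capped at the window duration (global average pooling per path); see
#'   [build_filter_banks()].
#' @param quality_factors Integer vector of wavelets per octave, one per
#'   order.
#' @param wavelet_family Only `"gabor"` (analytic Gaussian-windowed
#'   exponential) is implemented.
#' @param oversampling Non-negative integer; each increment halves the
#'   pooling stride (0 keeps the stride matched to the averaging scale).
#' @param log_transform Apply `log` to pooled coefficients in
#'   [scattering_features()].
#' @return A list of class `scattering_config`.
#' @export
scattering_config <- function(n_orders = 2, invariance_scale = 1,
                              quality_factors = c(8, 1),
                              wavelet_family = "gabor", oversampling = 0,
                              log_transform = FALSE) {
  if (!n_orders %in% c(1, 2)) abort("`n_orders` must be 1 or 2.")
  if (invariance_scale <= 0) abort("`invariance_scale` must be > 0.")
  if (length(quality_factors) < n_orders || any(quality_factors < 1)) {
    abort("Need one positive quality factor per order.")
  }
  wavelet_family <- match.arg(wavelet_family, "gabor")
  if (oversampling < 0) abort("`oversampling` must be >= 0.")
  structure(
    list(n_orders = n_orders, invariance_scale = invariance_scale,
         quality_factors = quality_factors[seq_len(n_orders)],
         wavelet_family = wavelet_family, oversampling = oversampling,
         log_transform = log_transform),
    class = "scattering_config"
  )
}

# Gabor wavelet magnitudes on the one-sided frequency grid, with the
# Morlet-style DC-cancellation term so psi_hat(0) = 0 exactly.
gabor_hat <- function(freq, fc, sigma) {
  kappa <- exp(-fc^2 / (2 * sigma^2))
  exp(-(freq - fc)^2 / (2 * sigma^2)) - kappa * exp(-freq^2 / (2 * sigma^2))
}

#' Build the Gabor filter banks for a scattering network
#'
#' One bank per order. Bank `k` holds analytic Gabor wavelets whose centre
#' frequencies are geometrically spaced at `2^(1/Q_k)` from just below the
#' Nyquist frequency down to `1 / T_eff`, with bandwidths chosen so adjacent
#' filters cross near -3 dB. `T_eff` is the invariance scale capped at the
#' signal duration; when capping occurs a message of class
#' `aewear_capped_invariance` is emitted once per build. Each bank is
#' normalised so its Littlewood-Paley sum peaks at 1; within the passband the
#' sum stays within 15% of unity.
#'
#' @param config A [scattering_config()].
#' @param fs Sampling rate in Hz.
#' @param n_samples Length of the windows the banks will analyse (>= 16).
#' @param cap_invariance Cap the invariance support at the window duration
#'   (default). With `FALSE`, an invariance scale exceeding the window is a
#'   configuration error.
#' @return A list of class `filter_banks`: per-order tibbles of filters
#'   (`center_frequency`, `bandwidth`, frequency-response list column), the
#'   low-pass filter response, the FFT grid length and pooling stride.
#' @export
build_filter_banks <- function(config, fs, n_samples, cap_invariance = TRUE) {
  if (n_samples < 16) abort("Need at least 16 samples.")
  duration <- n_samples / fs
  t_eff <- config$invariance_scale
  if (t_eff > duration) {
    if (!cap_invariance) {
      abort("Invariance scale exceeds the signal duration.",
            class = "aewear_config_error")
    }
    inform(sprintf(
      "Invariance scale %.3g s exceeds the %.3g s window; support capped at the window duration (global average pooling).",
      config$invariance_scale, duration), class = "aewear_capped_invariance")
    t_eff <- duration
  }
  n_fft <- n_samples
  freq <- seq(0, n_fft - 1) / n_fft * fs
  pos <- freq <= fs / 2          # analytic filters live here
  f_min <- 1 / t_eff
  sigma_phi <- 1 / (pi * t_eff)
  phi <- exp(-pmin(freq, fs - freq)^2 / (2 * sigma_phi^2))
  banks <- purrr::map(config$quality_factors, function(q) {
    f_max <- fs / 2 * 2^(-1 / (2 * q))
    n_filt <- max(1L, 1L + floor(q * log2(f_max / f_min)))
    fc <- f_max * 2^(-(seq_len(n_filt) - 1L) / q)
    sigma <- fc * (1 - 2^(-1 / q)) / (2 * sqrt(log(2)))
    resp <- purrr::map2(fc, sigma, function(f0, s0) {
      h <- numeric(n_fft)
      h[pos] <- gabor_hat(freq[pos], f0, s0)
      h
    })
    # Littlewood-Paley equalisation: dividing by sqrt(lp + delta) flattens
    # the energy coverage to ~1 across the passband (a lone Gaussian per
    # octave otherwise ripples by ~25% at Q = 1) and rolls it off smoothly
    # outside, keeping the bank non-expansive.
    lp <- Reduce(`+`, purrr::map(resp, ~ .x^2))
    delta <- 0.01 * max(lp)
    eq <- 1 / sqrt(lp + delta)
    resp <- purrr::map(resp, ~ .x * eq)
    bank <- tibble(center_frequency = fc,
                   bandwidth = 2 * sqrt(2 * log(2)) * sigma,
                   response = resp)
    attr(bank, "response_matrix") <- do.call(cbind, resp)
    bank
  })
  structure(
    list(banks = banks, lowpass = phi, n_fft = n_fft, n_samples = n_samples,
         fs = fs, t_eff = t_eff,
         stride = max(1L, floor(t_eff * fs / 2^config$oversampling)),
         config = config),
    class = "filter_banks"
  )
}

# Littlewood-Paley sum of one bank (squared filter magnitudes) on the
# frequency grid.
littlewood_paley <- function(fb, order = 1) {
  Reduce(`+`, purrr::map(fb$banks[[order]]$response, ~ .x^2))
}


#' Deep wavelet scattering transform of one window
#'
#' Computes the scattering coefficients of `x`:
#' order 0 is the low-pass average of the signal itself; order 1 takes the
#' complex modulus of each first-bank wavelet convolution and averages it;
#' order 2 re-filters each first-order modulus with the second bank (on
#' frequency-decreasing paths only), takes the modulus again and averages.
#' Convolutions are periodic (frequency-domain multiplication on the window
#' period), which makes the modulus envelopes exactly covariant to circular
#' shifts; averaged series are subsampled at the pooling stride. When the
#' invariance support is capped at the window duration each path is globally
#' average-pooled to a single value (the plain time mean, since the low-pass
#' filter has unit DC gain).
#'
#' @param x Numeric vector (finite, non-empty) or an [ae_signal()].
#' @param fs Sampling rate in Hz (ignored when `x` is an `ae_signal`).
#' @param config A [scattering_config()].
#' @param banks Optional precomputed [build_filter_banks()] result matching
#'   `length(x)`; building the banks once and reusing them is much faster
#'   when transforming many windows.
#' @return An object of class `scatter_matrix`: pooled coefficient series
#'   `s0`, `s1` (matrix, one row per first-order path), `s2` (matrix, one row
#'   per admissible `(j1, j2)` path) plus path metadata tibbles.
#' @export
scattering_transform <- function(x, fs = NULL, config = scattering_config(),
                                 banks = NULL) {
  if (inherits(x, "ae_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  if (length(x) == 0) abort("Empty input.")
  if (!all(is.finite(x))) abort("Non-finite samples.")
  if (is.null(banks)) {
    banks <- build_filter_banks(config, fs, length(x))
  } else if (banks$n_samples != length(x)) {
    abort("`banks` were built for a different window length.")
  }
  n <- length(x)
  stride <- min(banks$stride, n)
  pool_idx <- seq(1L, n, by = stride)
  # Low-pass average then subsample at the pooling stride; operates on a
  # whole matrix of modulus series (columns) at once.
  pool_mat <- function(u_mat) {
    if (length(pool_idx) == 1) {
      # capped invariance: global average pooling. The period mean of the
      # low-pass-filtered series equals the plain mean of the series since
      # the low-pass filter has unit DC gain.
      matrix(colMeans(u_mat), nrow = 1)
    } else {
      y <- Re(stats::mvfft(stats::mvfft(u_mat) * banks$lowpass,
                           inverse = TRUE)) / banks$n_fft
      y[pool_idx, , drop = FALSE]
    }
  }
  bank1 <- banks$banks[[1]]
  xhat <- fft(x)
  u1 <- Mod(stats::mvfft(attr(bank1, "response_matrix") * xhat,
                         inverse = TRUE) / banks$n_fft)
  paths1 <- tibble(j1 = seq_len(nrow(bank1)),
                   f1 = bank1$center_frequency,
                   bw1 = bank1$bandwidth)
  u2_cols <- NULL
  paths2 <- tibble(j1 = integer(0), j2 = integer(0),
                   f1 = numeric(0), f2 = numeric(0))
  if (config$n_orders >= 2) {
    bank2 <- banks$banks[[2]]
    rm2 <- attr(bank2, "response_matrix")
    adm_list <- purrr::map(bank1$bandwidth,
                           ~ which(bank2$center_frequency < .x))
    keep <- which(lengths(adm_list) > 0)
    if (length(keep) > 0) {
      u1hat <- stats::mvfft(u1[, keep, drop = FALSE])
      u2_list <- purrr::map(seq_along(keep), function(i) {
        adm <- adm_list[[keep[i]]]
        Mod(stats::mvfft(rm2[, adm, drop = FALSE] * u1hat[, i],
                         inverse = TRUE) / banks$n_fft)
      })
      u2_cols <- do.call(cbind, u2_list)
      meta <- purrr::map(keep, function(j1) {
        adm <- adm_list[[j1]]
        cbind(j1, adm, bank1$center_frequency[j1],
              bank2$center_frequency[adm])
      })
      m <- do.call(rbind, meta)
      paths2 <- tibble(j1 = as.integer(m[, 1]), j2 = as.integer(m[, 2]),
                       f1 = m[, 3], f2 = m[, 4])
    }
  }
  pooled <- pool_mat(cbind(x, u1, u2_cols))
  s0 <- pooled[, 1]
  s1 <- t(pooled[, 1 + seq_len(ncol(u1)), drop = FALSE])
  s2 <- NULL
  if (!is.null(u2_cols)) {
    s2 <- t(pooled[, 1 + ncol(u1) + seq_len(ncol(u2_cols)),
                   drop = FALSE])
  }
  structure(
    list(s0 = s0, s1 = s1, s2 = s2, paths1 = paths1, paths2 = paths2,
         pool_times = (pool_idx - 1) / fs, fs = fs, config = config),
    class = "scatter_matrix"
  )
}

#' Pool a scatter matrix into a fixed-length feature vector
#'
#' Time-averages each path's pooled coefficients and concatenates them in a
#' fixed, documented order: S0 first, then the first-order paths by
#' descending centre frequency, then the second-order paths lexicographically
#' (first-order path, then second-order filter, both by descending
#' frequency). The vector length is `1 + n_paths1 + n_paths2`.
#'
#' @param matrix A `scatter_matrix` from [scattering_transform()].
#' @param config A [scattering_config()]; `log_transform` applies
#'   `log(pmax(v, 1e-12))` to the pooled values.
#' @return Named numeric vector (`S0`, `S1_j`, `S2_j1_j2`).
#' @export
scattering_features <- function(matrix, config = matrix$config) {
  v <- c(S0 = mean(matrix$s0))
  if (!is.null(matrix$s1)) {
    s1 <- rowMeans(matrix$s1)
    names(s1) <- paste0("S1_", matrix$paths1$j1)
    v <- c(v, s1)
  }
  if (!is.null(matrix$s2)) {
    s2 <- rowMeans(matrix$s2)
    names(s2) <- paste0("S2_", matrix$paths2$j1, "_", matrix$paths2$j2)
    v <- c(v, s2)
  }
  if (isTRUE(config$log_transform)) v <- log(pmax(v, 1e-12))
  v
}

#' Scattering feature table for a windowed dataset
#'
#' Builds the filter banks once (all windows share a length) and applies the
#' transform plus pooling to every window.
#'
#' @param windows Output of [window_dataset()].
#' @param config A [scattering_config()].
#' @return A tibble with `signal_id`, `class`, `window_index` and one column
#'   per scattering path.
#' @export
scattering_table <- function(windows, config = scattering_config()) {
  n <- length(windows$samples[[1]])
  fs <- windows$fs[1]
  banks <- suppressMessages(build_filter_banks(config, fs, n))
  feats <- purrr::map(windows$samples, function(w) {
    scattering_features(scattering_transform(w, fs, config, banks = banks),
                        config)
  })
  dplyr::bind_cols(
    windows[c("signal_id", "class", "window_index")],
    dplyr::bind_rows(purrr::map(feats, ~ as_tibble(as.list(.x))))
  )
}
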