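#' Parameters of the handcrafted feature bank
#'
#' Bundles every tunable of the feature bank. The defaults follow common
#' practice for AE/biosignal feature extraction: a 1 microvolt threshold for
#' the counting features (zero crossings, slope-sign changes, peaks), sample
#' entropy with template length `m = 2` and tolerance `r = 0.2` times the
#' window SD, Higuchi fractal dimension with `Kmax = 10`, DFA box sizes 30 to
#' 300 in steps of 10 with first-order detrending, an AR(4) Burg model, and a
#' Welch PSD (Hann window, 4096-sample segments, 50% overlap) for the
#' spectral features.
#'
#' @param threshold Volts; gate for ZC, SSC and NP counting (WL is the pure
#'   cumulative absolute difference and ignores it).
#' @param sampen_m Sample-entropy template length (>= 1).
#' @param sampen_r Sample-entropy tolerance as a fraction of the window SD.
#' @param hfd_kmax Maximum decimation for the Higuchi estimate (>= 2).
#' @param dfa_box_sizes Strictly increasing integer box sizes; the largest
#'   must stay below a quarter of the window length.
#' @param ar_order Autoregressive model order.
#' @param ar_emit `"all"` emits AR1..AR4; `"last"` emits only the highest
#'   order coefficient (in AR1, with AR2..AR4 absent).
#' @param psd_method `"welch"` or `"periodogram"`.
#' @param psd_segment Welch segment length in samples (capped at the window
#'   length).
#' @param psd_overlap Welch segment overlap fraction in `[0, 1)`.
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(threshold = 1e-6, sampen_m = 2, sampen_r = 0.2,
                           hfd_kmax = 10, dfa_box_sizes = seq(30, 300, 10),
                           ar_order = 4, ar_emit = c("all", "last"),
                           psd_method = c("welch", "periodogram"),
                           psd_segment = 4096, psd_overlap = 0.5) {
  ar_emit <- match.arg(ar_emit)
  psd_method <- match.arg(psd_method)
  if (threshold < 0) abort("`threshold` must be >= 0.")
  if (sampen_m < 1) abort("`sampen_m` must be >= 1.")
  if (hfd_kmax < 2) abort("`hfd_kmax` must be >= 2.")
  dfa_box_sizes <- as.integer(dfa_box_sizes)
  if (any(diff(dfa_box_sizes) <= 0) || any(dfa_box_sizes < 4)) {
    abort("`dfa_box_sizes` must be strictly increasing integers >= 4.")
  }
  if (psd_overlap < 0 || psd_overlap >= 1) {
    abort("`psd_overlap` must lie in [0, 1).")
  }
  structure(
    list(threshold = threshold, sampen_m = sampen_m, sampen_r = sampen_r,
         hfd_kmax = hfd_kmax, dfa_box_sizes = dfa_box_sizes,
         ar_order = ar_order, ar_emit = ar_emit, psd_method = psd_method,
         psd_segment = psd_segment, psd_overlap = psd_overlap),
    class = "feature_params"
  )
}

#' Time-domain amplitude features
#'
#' Computes the eight time-domain members of the feature bank:
#' \describe{
#'   \item{MAV}{mean absolute value, `mean(|x|)`.}
#'   \item{WL}{waveform length, the cumulative absolute first difference.}
#'   \item{ZC}{threshold-gated zero crossings: sign changes between
#'     consecutive samples whose jump is at least `threshold`.}
#'   \item{SSC}{slope-sign changes across three consecutive samples, gated by
#'     `threshold` on the larger adjacent difference.}
#'   \item{RMS}{root mean square.}
#'   \item{NP}{number of strict local maxima with value >= `threshold`.}
#'   \item{SSI}{simple squared integral, `sum(x^2)`.}
#'   \item{VAR}{unbiased sample variance.}
#' }
#'
#' @param x Numeric vector (length >= 3; SSC is undefined below that).
#' @param params A [feature_params()].
#' @return Named numeric vector with elements MAV, WL, ZC, SSC, RMS, NP,
#'   SSI, VAR.
#' @export
extract_time_features <- function(x, params = feature_params()) {
  if (length(x) < 3) abort("Need at least 3 samples (SSC undefined).")
  thr <- params$threshold
  d <- diff(x)
  x0 <- x[-length(x)]
  x1 <- x[-1]
  zc <- sum(x0 * x1 < 0 & abs(d) >= thr)
  mid <- x[2:(length(x) - 1)]
  dl <- mid - x[1:(length(x) - 2)]
  dr <- mid - x[3:length(x)]
  ssc <- sum(dl * dr > 0 & pmax(abs(dl), abs(dr)) >= thr)
  np <- sum(mid > x[1:(length(x) - 2)] & mid > x[3:length(x)] & mid >= thr)
  c(MAV = mean(abs(x)), WL = sum(abs(d)), ZC = zc, SSC = ssc,
    RMS = sqrt(mean(x^2)), NP = np, SSI = sum(x^2), VAR = var(x))
}

# Welch (or plain periodogram) one-sided PSD. Returns freq (Hz) and power.
psd_estimate <- function(x, fs, params) {
  n <- length(x)
  if (params$psd_method == "periodogram") {
    seg_len <- n
    hop <- n
  } else {
    seg_len <- min(params$psd_segment, n)
    hop <- max(1L, floor(seg_len * (1 - params$psd_overlap)))
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / seg_len)
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  p <- acc[1:(seg_len %/% 2 + 1)] / length(starts)
  list(freq = (0:(seg_len %/% 2)) * fs / seg_len, power = p)
}

#' Frequency-domain features
#'
#' \describe{
#'   \item{MF}{median frequency: the smallest frequency at which the
#'     cumulative PSD reaches half the total power.}
#'   \item{PF}{peak frequency: the PSD-maximising frequency bin (lowest bin
#'     on ties).}
#'   \item{Ceps}{maximum of the real cepstrum over quefrency indices
#'     `1..N/2`, the zero quefrency (overall log-energy) excluded.}
#' }
#' For an all-zero window all three are defined as 0.
#'
#' @param x Numeric vector, length >= 8.
#' @param fs Sampling rate in Hz.
#' @param params A [feature_params()].
#' @return Named numeric vector with elements MF, PF, Ceps.
#' @export
extract_frequency_features <- function(x, fs, params = feature_params()) {
  if (length(x) < 8) abort("Need at least 8 samples for spectral features.")
  if (fs <= 0) abort("`fs` must be positive.")
  if (all(x == 0)) return(c(MF = 0, PF = 0, Ceps = 0))
  psd <- psd_estimate(x, fs, params)
  total <- sum(psd$power)
  mf <- psd$freq[which(cumsum(psd$power) >= total / 2)[1]]
  pf <- psd$freq[which.max(psd$power)]
  n <- length(x)
  mag <- Mod(fft(x))
  mag[mag == 0] <- .Machine$double.xmin
  ceps <- Re(fft(log(mag), inverse = TRUE)) / n
  q <- ceps[2:(n %/% 2 + 1)]
  c(MF = mf, PF = pf, Ceps = max(q))
}

#' Fit an autoregressive model by the Burg method
#'
#' Coefficients are in prediction form, `x_t ~ sum_k a_k * x_(t-k)`, estimated
#' on the demeaned window by Burg's recursion ([stats::ar.burg()]). A
#' zero-variance window yields all-zero coefficients with an informational
#' note.
#'
#' @param x Numeric vector, length > 2 * order.
#' @param params A [feature_params()]; `ar_order` and `ar_emit` are used.
#' @return Named numeric vector AR1..AR`p` (or just the last coefficient when
#'   `ar_emit = "last"`).
#' @export
fit_ar4 <- function(x, params = feature_params()) {
  p <- params$ar_order
  if (length(x) <= 2 * p) abort("Window too short for the AR fit.")
  if (sd(x) == 0) {
    inform("Zero-variance window: AR coefficients set to 0.",
           class = "aewear_degenerate")
    coefs <- rep(0, p)
  } else {
    coefs <- as.numeric(ar(x, aic = FALSE, order.max = p, method = "burg",
                           demean = TRUE)$ar)
  }
  if (params$ar_emit == "last") {
    c(AR1 = coefs[p])
  } else {
    stats::setNames(coefs, paste0("AR", seq_len(p)))
  }
}

#' Complexity and fractal features
#'
#' \describe{
#'   \item{SampEn}{sample entropy `-ln(A/B)` with template length `m`,
#'     tolerance `r * SD(x)`, Chebyshev distance, self-matches excluded.
#'     Degenerate windows (zero SD, or no template matches) return 0 with an
#'     informational note.}
#'   \item{MFL}{maximum fractal length, `log10(sqrt(sum(diff(x)^2)))`; for a
#'     constant window the value is floored at `log10` of the smallest
#'     positive double.}
#'   \item{HFD}{Higuchi fractal dimension over decimations `k = 1..Kmax`
#'     (slope of log mean curve length against `log(1/k)`).}
#'   \item{DFA}{detrended fluctuation exponent: slope of `log F(n)` vs
#'     `log n` over the configured box sizes, with per-box linear detrending
#'     of the integrated, mean-removed series.}
#' }
#'
#' @param x Numeric vector; must be longer than twice the largest DFA box.
#' @param params A [feature_params()].
#' @return Named numeric vector with elements SampEn, MFL, HFD, DFA.
#' @export
extract_complexity_features <- function(x, params = feature_params()) {
  c(SampEn = sample_entropy(x, params$sampen_m, params$sampen_r),
    MFL = mfl(x),
    HFD = higuchi_fd(x, params$hfd_kmax),
    DFA = dfa_exponent(x, params$dfa_box_sizes))
}

sample_entropy <- function(x, m = 2, r = 0.2) {
  s <- sd(x)
  if (s == 0) {
    inform("Zero-variance window: SampEn set to 0.",
           class = "aewear_degenerate")
    return(0)
  }
  counts <- sampen_counts(as.numeric(x), as.integer(m), r * s)
  if (counts[1] == 0 || counts[2] == 0) {
    inform("No template matches: SampEn set to 0.",
           class = "aewear_degenerate")
    return(0)
  }
  -log(counts[1] / counts[2])
}

mfl <- function(x) {
  wl2 <- sqrt(sum(diff(x)^2))
  if (wl2 == 0) {
    inform("Zero-variation window: MFL floored.",
           class = "aewear_degenerate")
    return(log10(.Machine$double.xmin))
  }
  log10(wl2)
}

higuchi_fd <- function(x, kmax = 10) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nk <- length(idx) - 1L
      if (nk < 1) { lm[m] <- NA; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nk * k) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  ok <- lk > 0
  if (sum(ok) < 2) return(0)
  ls_slope(log(1 / seq_len(kmax))[ok], log(lk[ok]))
}

# Ordinary least-squares slope of y on x.
ls_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

dfa_exponent <- function(x, box_sizes) {
  n <- length(x)
  if (max(box_sizes) > n / 4) {
    abort("Largest DFA box exceeds a quarter of the window length.")
  }
  y <- cumsum(x - mean(x))
  fn <- purrr::map_dbl(box_sizes, function(b) {
    nb <- n %/% b
    idx <- seq_len(nb * b)
    box <- rep(seq_len(nb), each = b)
    t <- rep(seq_len(b), nb)
    res <- unlist(lapply(split(seq_along(idx), box), function(ii) {
      yy <- y[idx[ii]]
      tt <- t[ii]
      fit <- stats::lm.fit(cbind(1, tt), yy)
      fit$residuals
    }), use.names = FALSE)
    sqrt(mean(res^2))
  })
  ok <- fn > 0
  if (sum(ok) < 2) return(0)
  ls_slope(log(box_sizes)[ok], log(fn[ok]))
}

#' Extract the full handcrafted feature vector for one window
#'
#' Concatenates the time-domain, autoregressive, complexity/fractal and
#' frequency-domain features into the 19-entry named vector
#' MAV, WL, ZC, SSC, RMS, AR1..AR4, SampEn, Ceps, MFL, HFD, DFA, MF, PF, NP,
#' SSI, VAR.
#'
#' @param window Numeric vector satisfying every sub-extractor's length
#'   precondition (in practice: longer than twice the largest DFA box).
#' @param fs Sampling rate in Hz.
#' @param params A [feature_params()].
#' @return Named numeric vector of length 19 (with default `ar_emit`).
#' @export
#' @examples
#' w <- rnorm(1500)
#' f <- extract_all(w, fs = 2e5)
#' names(f)
extract_all <- function(window, fs, params = feature_params()) {
  td <- extract_time_features(window, params)
  arc <- fit_ar4(window, params)
  cx <- extract_complexity_features(window, params)
  fq <- extract_frequency_features(window, fs, params)
  c(td[c("MAV", "WL", "ZC", "SSC", "RMS")], arc,
    cx[c("SampEn")], fq["Ceps"], cx[c("MFL", "HFD", "DFA")],
    fq[c("MF", "PF")], td[c("NP", "SSI", "VAR")])
}

#' Handcrafted feature table for a windowed dataset
#'
#' Applies [extract_all()] to every window and returns one row per window
#' with the metadata columns `signal_id`, `class`, `window_index` followed by
#' the 19 feature columns in their documented order.
#'
#' @param windows Output of [window_dataset()].
#' @param params A [feature_params()].
#' @return A tibble.
#' @export
feature_table <- function(windows, params = feature_params()) {
  feats <- purrr::map2(windows$samples, windows$fs,
                       ~ extract_all(.x, .y, params))
  dplyr::bind_cols(
    windows[c("signal_id", "class", "window_index")],
    dplyr::bind_rows(purrr::map(feats, ~ as_tibble(as.list(.x))))
  )
}
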