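test_that("time features vanish on the zero signal and match hand cases", {
  z <- extract_time_features(rep(0, 4))
  expect_true(all(z == 0))
  f <- extract_time_features(c(1, -1, 1, -1))
  expect_equal(unname(f["ZC"]), 3)
  expect_equal(unname(f["WL"]), 6)
  expect_equal(unname(f["MAV"]), 1)
  expect_equal(unname(f["RMS"]), 1)
  expect_error(extract_time_features(c(1, 2)), "3 samples")
})

test_that("every feature matches its brute-force oracle on random windows", {
  params <- feature_params(dfa_box_sizes = seq(8, 40, 4))
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(200:600, 1))
    x <- withr::with_seed(1000 + s, rnorm(n))
    td <- extract_time_features(x, params)
    expect_equal(td, oracle_time_features(x, params$threshold)[names(td)],
                 tolerance = 1e-12)
    fq <- extract_frequency_features(x, fs = 1000, params)
    expect_equal(unname(fq["MF"]), oracle_mf(x, 1000), tolerance = 1e-12)
    expect_equal(unname(fq["PF"]), oracle_pf(x, 1000), tolerance = 1e-12)
    expect_equal(unname(fq["Ceps"]), oracle_ceps(x), tolerance = 1e-12)
    cx <- extract_complexity_features(x, params)
    expect_equal(unname(cx["SampEn"]), oracle_sampen(x),
                 tolerance = 1e-12)
    expect_equal(unname(cx["MFL"]), log10(sqrt(sum(diff(x)^2))),
                 tolerance = 1e-12)
    expect_equal(unname(cx["HFD"]), oracle_higuchi(x), tolerance = 1e-12)
    expect_equal(unname(cx["DFA"]), oracle_dfa(x, params$dfa_box_sizes),
                 tolerance = 1e-10)
    arc <- fit_ar4(x, params)
    expect_equal(unname(arc), oracle_burg(x, 4), tolerance = 1e-10)
  }
})

test_that("spectral features localise tones", {
  fs <- 2000
  n <- 1024
  t <- (0:(n - 1)) / fs
  f0 <- 250 # exact bin for 4096-capped-to-1024 segments
  x <- sin(2 * pi * f0 * t)
  fq <- extract_frequency_features(x, fs)
  bin <- fs / n
  expect_lt(abs(fq[["PF"]] - f0), bin + 1e-9)
  expect_lt(abs(fq[["MF"]] - f0), bin + 1e-9)
  # two equal-power tones: median frequency must lie between them
  x2 <- sin(2 * pi * 125 * t) + sin(2 * pi * 437.5 * t)
  fq2 <- extract_frequency_features(x2, fs)
  expect_gte(fq2[["MF"]], 125)
  expect_lte(fq2[["MF"]], 437.5)
  # all-zero input: degenerate convention
  expect_equal(unname(extract_frequency_features(numeric(64), fs)),
               c(0, 0, 0))
})

test_that("an echo produces a cepstral peak at the echo lag", {
  # white-noise source: its log-spectrum is flat on average, so the echo
  # term dominates the cepstrum away from quefrency zero
  withr::with_seed(3, {
    n <- 512
    s <- rnorm(n)
    tau <- 40
    x <- s + 0.5 * c(rep(0, tau), s[1:(n - tau)])
  })
  mag <- Mod(fft(x))
  mag[mag == 0] <- .Machine$double.xmin
  ceps <- Re(fft(log(mag), inverse = TRUE)) / length(x)
  q <- ceps[2:(length(x) %/% 2 + 1)]
  expect_equal(which.max(q), tau)
  fq <- extract_frequency_features(x, fs = 1000)
  expect_equal(unname(fq["Ceps"]), max(q), tolerance = 1e-12)
})

test_that("fractal estimators recover known exponents", {
  # straight line has dimension 1; white noise is close to 2
  expect_lt(abs(higuchi_line <- extract_complexity_features(
    as.numeric(1:2000), feature_params(dfa_box_sizes = seq(8, 64, 8))
  )[["HFD"]] - 1), 0.05)
  hfd_wn <- withr::with_seed(7, extract_complexity_features(
    rnorm(5000), feature_params(dfa_box_sizes = seq(8, 64, 8)))[["HFD"]])
  expect_gt(hfd_wn, 1.9)
  expect_lt(hfd_wn, 2.05)
})

test_that("DFA recovers white and integrated-noise scaling exponents", {
  boxes <- seq(30, 300, 10)
  alphas <- vapply(1:20, function(s) {
    x <- withr::with_seed(s, rnorm(5000))
    c(aewear:::dfa_exponent(x, boxes),
      aewear:::dfa_exponent(cumsum(x), boxes))
  }, numeric(2))
  expect_lt(abs(mean(alphas[1, ]) - 0.5), 0.05)
  expect_lt(abs(mean(alphas[2, ]) - 1.5), 0.1)
})

test_that("Burg AR estimation recovers simulated processes", {
  x <- withr::with_seed(11, as.numeric(stats::arima.sim(list(ar = 0.7),
                                                        10000)))
  arc <- fit_ar4(x)
  expect_lt(abs(arc[["AR1"]] - 0.7), 0.05)
  wn <- withr::with_seed(12, rnorm(10000))
  expect_true(all(abs(fit_ar4(wn)) < 0.05))
  x64 <- withr::with_seed(13, rnorm(64))
  expect_equal(unname(fit_ar4(x64)), oracle_burg(x64, 4),
               tolerance = 1e-10)
  expect_equal(names(fit_ar4(x64, feature_params(ar_emit = "last"))), "AR1")
})

test_that("degenerate windows fall back to documented conventions", {
  params <- feature_params(dfa_box_sizes = seq(8, 24, 8))
  expect_message(v <- extract_complexity_features(rep(1, 200), params),
                 class = "aewear_degenerate")
  expect_equal(unname(v["SampEn"]), 0)
  expect_equal(unname(v["MFL"]), log10(.Machine$double.xmin))
  expect_message(a <- fit_ar4(rep(2, 100)), class = "aewear_degenerate")
  expect_true(all(a == 0))
  expect_error(aewear:::dfa_exponent(rnorm(100), c(10, 60)), "box")
})

test_that("features scale as documented under amplitude scaling", {
  params0 <- feature_params(threshold = 0, dfa_box_sizes = seq(8, 40, 8))
  x <- withr::with_seed(21, rnorm(400))
  c0 <- 3.7
  a <- extract_all(x, fs = 1000, params0)
  b <- extract_all(c0 * x, fs = 1000, params0)
  for (nm in c("MAV", "RMS", "WL")) {
    expect_equal(b[[nm]], c0 * a[[nm]], tolerance = 1e-10)
  }
  expect_equal(b[["MFL"]], a[["MFL"]] + log10(c0), tolerance = 1e-10)
  for (nm in c("ZC", "SSC", "NP", "HFD", "DFA", "SampEn")) {
    expect_equal(b[[nm]], a[[nm]], tolerance = 1e-8)
  }
})

test_that("extract_all returns the 19-entry schema deterministically", {
  x <- withr::with_seed(31, rnorm(1500))
  f1 <- extract_all(x, fs = 2e5)
  expect_equal(names(f1),
               c("MAV", "WL", "ZC", "SSC", "RMS", "AR1", "AR2", "AR3",
                 "AR4", "SampEn", "Ceps", "MFL", "HFD", "DFA", "MF", "PF",
                 "NP", "SSI", "VAR"))
  expect_true(all(is.finite(f1)))
  expect_identical(f1, extract_all(x, fs = 2e5))
  # a pure 250 kHz tone at 2 MHz sampling peaks at 250 kHz
  fs <- 2e6
  tone <- sin(2 * pi * 250e3 * (0:99999) / fs)
  ft <- extract_all(tone, fs = fs)
  expect_lt(abs(ft[["PF"]] - 250e3), fs / 4096 + 1e-6)
})

test_that("abrasive windows carry more RMS than adhesive windows", {
  fx <- ae_fixture()
  rms <- tapply(fx$features$RMS, fx$features$class, mean)
  expect_gt(rms[["abrasive"]], rms[["adhesive"]])
})
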