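# Independent brute-force oracles used across the suite. Each one is written
# as a plain index-loop transcription of the feature definition, kept free of
# the package's own code paths.

oracle_time_features <- function(x, thr) {
  n <- length(x)
  mav <- sum(abs(x)) / n
  wl <- 0
  for (i in 2:n) wl <- wl + abs(x[i] - x[i - 1])
  zc <- 0
  for (i in 1:(n - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= thr) zc <- zc + 1
  }
  ssc <- 0
  np <- 0
  for (i in 2:(n - 1)) {
    dl <- x[i] - x[i - 1]
    dr <- x[i] - x[i + 1]
    if (dl * dr > 0 && max(abs(dl), abs(dr)) >= thr) ssc <- ssc + 1
    if (x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] >= thr) np <- np + 1
  }
  rms <- sqrt(sum(x^2) / n)
  ssi <- sum(x^2)
  vr <- sum((x - mean(x))^2) / (n - 1)
  c(MAV = mav, WL = wl, ZC = zc, SSC = ssc, RMS = rms, NP = np,
    SSI = ssi, VAR = vr)
}

oracle_welch_psd <- function(x, fs, seg_len, overlap) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  hop <- max(1, floor(seg_len * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / seg_len)
  starts <- seq(1, n - seg_len + 1, by = hop)
  acc <- numeric(seg_len)
  for (s in starts) acc <- acc + Mod(fft(x[s:(s + seg_len - 1)] * w))^2
  list(freq = (0:(seg_len %/% 2)) * fs / seg_len,
       power = acc[1:(seg_len %/% 2 + 1)] / length(starts))
}

oracle_mf <- function(x, fs, seg_len = 4096, overlap = 0.5) {
  psd <- oracle_welch_psd(x, fs, seg_len, overlap)
  csum <- cumsum(psd$power)
  psd$freq[which(csum >= csum[length(csum)] / 2)[1]]
}

oracle_pf <- function(x, fs, seg_len = 4096, overlap = 0.5) {
  psd <- oracle_welch_psd(x, fs, seg_len, overlap)
  psd$freq[which.max(psd$power)]
}

oracle_ceps <- function(x) {
  n <- length(x)
  mag <- Mod(fft(x))
  mag[mag == 0] <- .Machine$double.xmin
  ceps <- Re(fft(log(mag), inverse = TRUE)) / n
  max(ceps[2:(n %/% 2 + 1)])
}

oracle_sampen <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  A <- 0
  B <- 0
  last <- n - m
  for (i in 1:(last - 1)) {
    js <- (i + 1):last
    dmax <- abs(x[i] - x[js])
    for (k in 1:(m - 1)) {
      dmax <- pmax(dmax, abs(x[i + k] - x[js + k]))
    }
    hit <- dmax <= r
    B <- B + sum(hit)
    A <- A + sum(pmax(dmax[hit], abs(x[i + m] - x[js[hit] + m])) <= r)
  }
  if (A == 0 || B == 0) return(0)
  -log(A / B)
}

oracle_higuchi <- function(x, kmax = 10) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in 1:kmax) {
    lm <- c()
    for (m in 1:k) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) next
      s <- 0
      for (i in 2:length(idx)) s <- s + abs(x[idx[i]] - x[idx[i - 1]])
      lm <- c(lm, s * (n - 1) / ((length(idx) - 1) * k) / k)
    }
    lk[k] <- mean(lm)
  }
  xs <- log(1 / (1:kmax))
  ys <- log(lk)
  sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
}

oracle_dfa <- function(x, boxes) {
  n <- length(x)
  y <- cumsum(x - mean(x))
  fn <- numeric(length(boxes))
  for (bi in seq_along(boxes)) {
    b <- boxes[bi]
    nb <- n %/% b
    ss <- 0
    for (j in 1:nb) {
      seg <- y[((j - 1) * b + 1):(j * b)]
      t <- 1:b
      fit <- lm(seg ~ t)
      ss <- ss + sum(resid(fit)^2)
    }
    fn[bi] <- sqrt(ss / (nb * b))
  }
  xs <- log(boxes)
  ys <- log(fn)
  sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
}

oracle_burg <- function(x, p) {
  x <- x - mean(x)
  n <- length(x)
  f <- x[2:n]
  b <- x[1:(n - 1)]
  a <- c()
  for (m in 1:p) {
    k <- 2 * sum(f * b) / (sum(f^2) + sum(b^2))
    a <- if (m == 1) k else c(a - k * rev(a), k)
    fn <- f[-1] - k * b[-1]
    bn <- b[-length(b)] - k * f[-length(f)]
    f <- fn
    b <- bn
  }
  a
}

# Double-loop multiclass ReliefF, k nearest hits/misses by Manhattan
# distance on range-normalised features, miss classes weighted by prior
# renormalised over the other classes.
oracle_relieff <- function(x, y, k) {
  y <- factor(y)
  n <- nrow(x)
  p <- ncol(x)
  rng <- apply(x, 2, max) - apply(x, 2, min)
  rng[rng == 0] <- Inf
  xn <- x
  for (j in 1:p) xn[, j] <- (x[, j] - min(x[, j])) / rng[j]
  priors <- table(y) / n
  w <- numeric(p)
  for (i in 1:n) {
    d <- numeric(n)
    for (j in 1:n) d[j] <- sum(abs(xn[i, ] - xn[j, ]))
    d[i] <- Inf
    for (cl in levels(y)) {
      cand <- which(y == cl & is.finite(d))
      nb <- cand[order(d[cand])[1:k]]
      diffs <- numeric(p)
      for (a in 1:p) diffs[a] <- mean(abs(xn[nb, a] - xn[i, a]))
      if (cl == as.character(y[i])) {
        w <- w - diffs / n
      } else {
        w <- w + as.numeric(priors[cl]) /
          (1 - as.numeric(priors[as.character(y[i])])) * diffs / n
      }
    }
  }
  names(w) <- colnames(x)
  w
}

# Five well-separated Gaussian clusters in feature space (centroid distance
# much larger than the spread), used for benchmark sanity checks.
make_separable_clusters <- function(n_per_class = 40, p = 6, spread = 0.5,
                                    centroid_scale = 10, seed = 1) {
  withr::with_seed(seed, {
    classes <- paste0("c", 1:5)
    centers <- matrix(rnorm(5 * p), nrow = 5) * centroid_scale
    x <- do.call(rbind, lapply(1:5, function(i) {
      sweep(matrix(rnorm(n_per_class * p, sd = spread), ncol = p),
            2, centers[i, ], "+")
    }))
    colnames(x) <- paste0("f", 1:p)
    list(x = x, y = factor(rep(classes, each = n_per_class)))
  })
}

# Small desk-scale synthetic study shared by several tests (cached per
# session): windows, handcrafted features and scattering features.
ae_fixture_env <- new.env(parent = emptyenv())

ae_fixture <- function() {
  if (is.null(ae_fixture_env$data)) {
    ds <- simulate_dataset(12, duration = 0.075, seed = 424242,
                           preset = "desk", difficulty = 0)
    w <- window_dataset(ds, 10)
    feats <- feature_table(w)
    dws <- scattering_table(w)
    ae_fixture_env$data <- list(dataset = ds, windows = w,
                                features = feats, dws = dws)
  }
  ae_fixture_env$data
}

# Naive scattering oracle: materialises every path by explicit circulant
# time-domain convolution with the banks' filters, modulus, convolution
# again, then low-pass pooling over the window.
oracle_scatter <- function(x, fs, config) {
  banks <- suppressMessages(build_filter_banks(config, fs, length(x)))
  n <- length(x)
  shift_idx <- (outer(0:(n - 1), 0:(n - 1), "-") %% n) + 1
  circ <- function(h) matrix(h[shift_idx], n, n)
  conv_c <- function(vec, resp) {
    h <- fft(resp, inverse = TRUE) / n
    as.vector(circ(h) %*% vec)
  }
  stride <- min(banks$stride, n)
  pool_pts <- seq(1, n, by = stride)
  phi_t <- fft(banks$lowpass, inverse = TRUE) / n
  phi_mat <- circ(phi_t)
  pool <- function(u) {
    y <- Re(as.vector(phi_mat %*% u))
    if (length(pool_pts) == 1) mean(y) else y[pool_pts]
  }
  bank1 <- banks$banks[[1]]
  bank2 <- banks$banks[[2]]
  u1 <- lapply(bank1$response, function(r) Mod(conv_c(x, r)))
  s1 <- do.call(rbind, lapply(u1, pool))
  s2 <- list()
  for (j1 in seq_len(nrow(bank1))) {
    adm <- which(bank2$center_frequency < bank1$bandwidth[j1])
    for (j2 in adm) {
      u2 <- Mod(conv_c(u1[[j1]], bank2$response[[j2]]))
      s2[[length(s2) + 1]] <- pool(u2)
    }
  }
  list(s0 = pool(x), s1 = s1, s2 = do.call(rbind, s2))
}

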