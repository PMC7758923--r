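test_that("moment features recover hand-computed population moments", {
  alt <- rep(c(1, -1), 50)                 # variance 1, kurtosis 1
  mf <- moment_features(alt)
  expect_equal(mf$variance, 1)
  expect_equal(mf$skewness, 0)
  expect_equal(mf$kurtosis, 1)
  expect_false(mf$degenerate)
  # symmetric data has zero skewness
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(moment_features(sym)$skewness, 0)
  # constants are flagged degenerate
  expect_true(moment_features(rep(2, 10))$degenerate)
})

test_that("spectral features locate peak and median frequency", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  sf <- spectral_features(sin(2 * pi * 5 * t), fs)
  bin <- fs / length(t)
  expect_lt(abs(sf$peak_freq - 5), bin + 1e-9)
  expect_lt(abs(sf$median_freq - 5), bin + 1e-9)
  expect_gt(sf$relpower_theta, 0.99)      # 5 Hz sits in theta (4-8 Hz)
  # white noise: median frequency near Nyquist/2 = 50 Hz on average
  set.seed(8)
  med <- replicate(50, spectral_features(rnorm(2 * fs), fs)$median_freq)
  expect_lt(abs(mean(med) - 50), 5)
  # all-zero input degenerates with zero powers
  z <- spectral_features(numeric(2 * fs), fs)
  expect_true(z$degenerate)
  expect_equal(z$total_energy, 0)
  expect_equal(z$power_delta, 0)
})

test_that("Petrosian fractal dimension matches the closed form", {
  expect_equal(petrosian_fd(rep(3.3, 50)), 1.0)
  # alternating series, N = 100: Nd = 98
  alt <- rep(c(0, 1), 50)
  expect_equal(petrosian_fd(alt), 2 / (2 + log10(100 / 139.2)),
               tolerance = 1e-12)
  # PFD grows with the number of sign changes at fixed N
  smooth <- sin(2 * pi * 2 * (0:99) / 100)
  expect_gt(petrosian_fd(alt), petrosian_fd(smooth))
})

test_that("petrosian and svd entropy match brute-force reimplementations", {
  pfd_brute <- function(x) {
    n <- length(x)
    d <- diff(x)
    nd <- 0
    last <- 0
    for (v in d) {
      s <- sign(v)
      if (s != 0) {
        if (last != 0 && s != last) nd <- nd + 1
        last <- s
      }
    }
    log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
  }
  svdent_brute <- function(x, d = 20, tau = 1) {
    x <- x - mean(x)
    n_rows <- length(x) - (d - 1) * tau
    m <- matrix(0, n_rows, d)
    for (i in seq_len(n_rows))
      m[i, ] <- x[i + (0:(d - 1)) * tau]
    sv <- svd(m)$d
    p <- sv / sum(sv)
    p <- p[p > 1e-15]
    -sum(p * log2(p))
  }
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(120 + i)
    expect_equal(petrosian_fd(x), pfd_brute(x), tolerance = 1e-9)
    expect_equal(svd_entropy(x), svdent_brute(x), tolerance = 1e-9)
  }
})

test_that("svd entropy hits its analytic anchors", {
  # constant series: embedding is rank deficient after demeaning -> 0
  expect_equal(svd_entropy(rep(5, 50), embed_dim = 2), 0)
  # pure sinusoid: two dominant singular values, about 1 bit
  t <- (0:2047) / 200
  e <- svd_entropy(sin(2 * pi * 5 * t))
  expect_lt(abs(e - 1), 0.2)
  # never exceeds log2(embed_dim)
  set.seed(10)
  for (d in c(2, 5, 20))
    expect_lte(svd_entropy(rnorm(500), embed_dim = d), log2(d) + 1e-12)
})

test_that("cross-channel correlation enumerates unordered pairs", {
  set.seed(11)
  x <- matrix(rnorm(10 * 200), 10)
  cc <- cross_channel_correlation(x)
  expect_length(cc$values, 45)
  expect_false(cc$degenerate)
  dup <- rbind(a = x[1, ], b = x[1, ], c = -x[1, ])
  cc2 <- cross_channel_correlation(dup)
  expect_equal(unname(cc2$values["a__b"]), 1)
  expect_equal(unname(cc2$values["a__c"]), -1)
  flat <- rbind(x[1, ], rep(1, 200))
  expect_true(cross_channel_correlation(flat)$degenerate)
})

test_that("temporal ratios track amplitude growth across the window", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  sine <- sin(2 * pi * 2 * t)
  x <- matrix(sine, 1)
  expect_equal(temporal_ratio(x, fs, "rms"), 1, tolerance = 0.01,
               ignore_attr = TRUE)
  grown <- sine
  grown[t >= 5] <- grown[t >= 5] * 10
  expect_equal(temporal_ratio(matrix(grown, 1), fs, "rms"), 10,
               tolerance = 0.05, ignore_attr = TRUE)
  # a crop straddling a synthetic transition has ratio > 1
  mrec <- toy_montaged(seed = 12, duration_s = 40, transition_s = 22)
  crops <- enumerate_crops(mrec, crop_spec(10, 1, 10))
  straddle <- which(crops$index$start_s == 17)   # window [17, 27)
  r <- temporal_ratio(crops$data[, , straddle], mrec$sampling_rate_hz, "rms")
  expect_true(mean(r) > 1)
})

test_that("feature vectors are deterministic, finite and offset-invariant", {
  mrec <- toy_montaged(seed = 13, duration_s = 30, transition_s = 15)
  crops <- enumerate_crops(mrec, crop_spec(10, 5, 10))
  f1 <- crop_feature_matrix(crops)
  f2 <- crop_feature_matrix(crops)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
  expect_true(all(nchar(colnames(f1)) > 0))
  # adding a constant offset to every sample changes nothing materially
  shifted <- crops
  shifted$data <- crops$data + 100
  f3 <- crop_feature_matrix(shifted)
  denom <- pmax(abs(f1), 1)
  expect_lt(max(abs(f3 - f1) / denom), 1e-6)
  # an all-zero crop yields a finite, flagged vector
  zc <- crops
  zc$data[] <- 0
  fz <- crop_feature_matrix(zc)
  expect_true(all(is.finite(fz)))
  expect_true(all(fz[, "degenerate_flag"] == 1))
})
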